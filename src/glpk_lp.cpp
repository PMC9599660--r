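#include <Rcpp.h>
#include <glpk.h>
#include <cmath>

using namespace Rcpp;

// Solve min/max c'x  s.t.  row_lb <= A x <= row_ub,  col_lb <= x <= col_ub.
// A is passed in triplet form (1-based row/col indices). Infinite bounds are
// encoded as +/-Inf. Returns primal solution, objective and a status string.
// [[Rcpp::export]]
List glpk_solve(NumericVector obj,
                IntegerVector ai, IntegerVector aj, NumericVector ax,
                int nrow, int ncol,
                NumericVector row_lb, NumericVector row_ub,
                NumericVector col_lb, NumericVector col_ub,
                bool maximize) {
  glp_prob *lp = glp_create_prob();
  glp_set_obj_dir(lp, maximize ? GLP_MAX : GLP_MIN);
  if (nrow > 0) glp_add_rows(lp, nrow);
  glp_add_cols(lp, ncol);

  for (int i = 0; i < nrow; ++i) {
    double lo = row_lb[i], hi = row_ub[i];
    int type;
    if (std::isinf(lo) && std::isinf(hi)) type = GLP_FR;
    else if (std::isinf(lo)) type = GLP_UP;
    else if (std::isinf(hi)) type = GLP_LO;
    else if (lo == hi) type = GLP_FX;
    else type = GLP_DB;
    glp_set_row_bnds(lp, i + 1, type, lo, hi);
  }
  for (int j = 0; j < ncol; ++j) {
    double lo = col_lb[j], hi = col_ub[j];
    int type;
    if (std::isinf(lo) && std::isinf(hi)) type = GLP_FR;
    else if (std::isinf(lo)) type = GLP_UP;
    else if (std::isinf(hi)) type = GLP_LO;
    else if (lo == hi) type = GLP_FX;
    else type = GLP_DB;
    glp_set_col_bnds(lp, j + 1, type, lo, hi);
    glp_set_obj_coef(lp, j + 1, obj[j]);
  }

  int nnz = ax.size();
  if (nnz > 0) {
    // GLPK uses 1-based arrays with element 0 unused
    std::vector<int> ia(nnz + 1), ja(nnz + 1);
    std::vector<double> ar(nnz + 1);
    for (int k = 0; k < nnz; ++k) {
      ia[k + 1] = ai[k];
      ja[k + 1] = aj[k];
      ar[k + 1] = ax[k];
    }
    glp_load_matrix(lp, nnz, ia.data(), ja.data(), ar.data());
  }

  glp_smcp parm;
  glp_init_smcp(&parm);
  parm.msg_lev = GLP_MSG_OFF;
  parm.tol_bnd = 1e-9;
  parm.tol_dj  = 1e-9;
  parm.presolve = GLP_OFF;
  int ret = glp_simplex(lp, &parm);

  std::string status;
  double objval = NA_REAL;
  NumericVector x(ncol, NA_REAL);
  if (ret != 0) {
    // numerical trouble: retry with presolver before giving up
    parm.presolve = GLP_ON;
    ret = glp_simplex(lp, &parm);
  }
  int st = glp_get_status(lp);
  if (ret == 0 && st == GLP_OPT) {
    status = "optimal";
    objval = glp_get_obj_val(lp);
    for (int j = 0; j < ncol; ++j) x[j] = glp_get_col_prim(lp, j + 1);
  } else if (st == GLP_NOFEAS || st == GLP_INFEAS) {
    status = "infeasible";
  } else if (st == GLP_UNBND) {
    status = "unbounded";
  } else {
    status = "failed";
  }

  glp_delete_prob(lp);
  return List::create(_["status"] = status,
                      _["objective"] = objval,
                      _["x"] = x);
}
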