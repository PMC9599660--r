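#' Solve a linear program
#'
#' Thin wrapper around the GLPK simplex solver. The problem is
#' \deqn{\min / \max \; c^T x \quad \text{s.t.} \quad rlb \le A x \le rub,
#'   \; lb \le x \le ub.}
#'
#' @param obj numeric objective coefficients (length = number of variables).
#' @param A constraint matrix (dense matrix or \code{Matrix} sparse matrix);
#'   may have zero rows.
#' @param row_lb,row_ub numeric row bounds; use \code{-Inf}/\code{Inf} for
#'   one-sided rows and equal values for equality rows.
#' @param col_lb,col_ub numeric variable bounds.
#' @param maximize logical; maximize instead of minimize.
#'
#' @return list with \code{status} ("optimal", "infeasible", "unbounded" or
#'   "failed"), \code{objective} and the primal vector \code{x}.
#' @keywords internal
solve_lp <- function(obj, A, row_lb, row_ub, col_lb, col_ub, maximize = TRUE) {
  ncol <- length(obj)
  if (is.null(A) || (is.matrix(A) && nrow(A) == 0L)) {
    trip <- list(i = integer(0), j = integer(0), x = numeric(0))
    nrow <- 0L
  } else {
    Asp <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                       "TsparseMatrix")
    trip <- list(i = Asp@i + 1L, j = Asp@j + 1L, x = Asp@x)
    nrow <- nrow(Asp)
    stopifnot(ncol(Asp) == ncol)
  }
  keep <- trip$x != 0
  res <- glpk_solve(as.numeric(obj),
                    as.integer(trip$i[keep]), as.integer(trip$j[keep]),
                    as.numeric(trip$x[keep]),
                    as.integer(nrow), as.integer(ncol),
                    as.numeric(row_lb), as.numeric(row_ub),
                    as.numeric(col_lb), as.numeric(col_ub),
                    isTRUE(maximize))
  res
}
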