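#' Coupling-coordination degree of the three subsystem scores
#'
#' The three-subsystem coupling-coordination model treats the natural,
#' economic, and social theme scores (each on \[0, 1\]) as coupled
#' subsystems and summarizes their balance and joint level:
#'
#' \deqn{C = \left[ \frac{U_1 U_2 U_3}{\left((U_1+U_2+U_3)/3\right)^3} \right]^{1/3}}
#' \deqn{T = \alpha_1 U_1 + \alpha_2 U_2 + \alpha_3 U_3, \qquad D = 100\sqrt{C\,T}}
#'
#' C is the geometric-to-arithmetic-mean ratio of the subsystems: by the
#' AM-GM inequality \eqn{C \le 1}, with equality exactly when all three are
#' equal (and positive). T is the weighted overall level, and D combines
#' balance and level, reported on the 0-100 scale the composite scores use.
#' When all subsystems are zero, C and D are defined as 0.
#'
#' @param u1,u2,u3 Numeric vectors of subsystem scores on \[0, 1\]
#'   (recycled to a common length). `NA` propagates.
#' @param alpha Coordination weight triple, nonnegative, summing to 1.
#'   Default equal weights.
#' @return A tibble with columns `C`, `T` (both on \[0, 1\]) and `D`
#'   (0-100).
#' @export
#' @examples
#' coupling_coordination(0.2, 0.4, 0.6)
#' coupling_coordination(0.5, 0.5, 0.5)  # perfectly balanced: C = 1
coupling_coordination <- function(u1, u2, u3, alpha = rep(1 / 3, 3)) {
  if (length(alpha) != 3 || any(!is.finite(alpha)) || any(alpha < 0)) {
    stop("alpha must be three nonnegative finite weights", call. = FALSE)
  }
  if (abs(sum(alpha) - 1) > 1e-8) {
    stop("alpha must sum to 1", call. = FALSE)
  }
  n <- max(length(u1), length(u2), length(u3))
  U <- cbind(rep_len(u1, n), rep_len(u2, n), rep_len(u3, n))
  bad <- which(!is.na(U) & (U < -1e-12 | U > 1 + 1e-12), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("subsystem score out of [0, 1]: %.6g", U[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  U <- pmin(pmax(U, 0), 1)

  m <- rowMeans(U)
  C <- ifelse(m > 0, (apply(U, 1, prod) / m^3)^(1 / 3), 0)
  C <- pmin(C, 1)  # guard AM-GM against roundoff
  Tt <- as.numeric(U %*% alpha)
  D <- 100 * sqrt(C * Tt)
  miss <- rowSums(is.na(U)) > 0
  C[miss] <- NA_real_; Tt[miss] <- NA_real_; D[miss] <- NA_real_
  tibble::tibble(C = C, T = Tt, D = D)
}
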