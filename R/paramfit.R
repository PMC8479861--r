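# Weighted linear least-squares parameterization of the correction term,
# the per-solvent surface-shift fit, and the error statistics used to
# evaluate the model.

#' Assemble the design matrix of a correction-term fit
#'
#' The correction is linear in its parameters, so fitting reduces to a
#' weighted linear least-squares problem. Each training row holds the
#' precomputed features of one (solute, solvent) record: the cavity volume
#' \code{volume}, per-element exposed-area sums in columns \code{S_<el>},
#' per-element induced-charge sums in columns \code{q_<el>}, the reference
#' solvation free energy \code{dg_ref}, the electrostatic energy
#' \code{e_elst} (both kcal/mol), an optional \code{weight} and an optional
#' subset label \code{subset} (one subset per solvent). The response is
#' \code{dg_ref - e_elst}; the unknowns are kappa per element, g per
#' element, and zeta.
#'
#' @param rows Data frame as described above.
#' @return List with \code{X} (n x p design), \code{y}, \code{w}, and
#'   \code{elements} (the element set, from the column names).
#' @export
assemble_design_matrix <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1)
  need <- c("dg_ref", "e_elst", "volume")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("training rows lack required columns: ", paste(miss, collapse = ", "))
  s_cols <- grep("^S_", names(rows), value = TRUE)
  q_cols <- grep("^q_", names(rows), value = TRUE)
  if (!length(s_cols))
    stop("no per-element area columns (S_<element>) found")
  els <- sub("^S_", "", s_cols)
  if (!setequal(els, sub("^q_", "", q_cols)))
    stop("area columns ", paste(s_cols, collapse = ","),
         " and charge columns ", paste(q_cols, collapse = ","),
         " cover different element sets")
  q_cols <- paste0("q_", els)
  X <- cbind(as.matrix(rows[s_cols]), as.matrix(rows[q_cols]),
             zeta = rows$volume)
  colnames(X) <- c(paste0("kappa_", els), paste0("g_", els), "zeta")
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- rows$dg_ref - rows$e_elst
  w <- if ("weight" %in% names(rows)) rows$weight else rep(1, nrow(rows))
  if (any(w <= 0)) stop("weights must be positive")
  list(X = X, y = y, w = w, elements = els)
}

#' Fit correction-term parameters by weighted least squares
#'
#' Minimizes \eqn{\sum_i w_i (y_i - x_i^T \beta)^2} for the linear
#' correction parameters (kappa per element, g per element, zeta) by a QR
#' decomposition of the weighted design. The solution is closed-form and
#' deterministic; uniform rescaling of the weights leaves it unchanged.
#'
#' @param rows Training data frame (see
#'   \code{\link{assemble_design_matrix}}), or a list \code{(X, y, w)}.
#' @param weights Optional per-row weights overriding the \code{weight}
#'   column.
#' @return Object of class \code{"solv_fit"} with components
#'   \code{coefficients}, \code{se}, \code{residuals} (unweighted),
#'   \code{fitted}, \code{sigma}, \code{vcov}, \code{df.residual},
#'   \code{elements}, \code{stats} (error statistics of the fit).
#' @examples
#' p <- default_parameters()
#' tr <- make_synthetic_training(p, n = 30, noise_sd = 0, seed = 7)
#' fit <- solv_fit(tr)
#' coef(fit)[["zeta"]]
#' @export
solv_fit <- function(rows, weights = NULL) {
  d <- if (is.data.frame(rows)) assemble_design_matrix(rows) else rows
  X <- d$X; y <- d$y
  w <- if (!is.null(weights)) weights else d$w
  n <- nrow(X); p <- ncol(X)
  if (n < p)
    stop("need at least as many rows (", n, ") as unknowns (", p, ")")
  sw <- sqrt(w)
  qrd <- qr(X * sw)
  if (qrd$rank < p) {
    bad <- colnames(X)[qrd$pivot[(qrd$rank + 1):p]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrd, y * sw)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  dfres <- n - p
  sigma2 <- if (dfres > 0) sum(w * res^2) / dfres else NA_real_
  R <- qr.R(qrd)[, order(qrd$pivot), drop = FALSE]
  XtWXinv <- chol2inv(chol(crossprod(R)))
  dimnames(XtWXinv) <- list(colnames(X), colnames(X))
  vc <- sigma2 * XtWXinv
  structure(list(coefficients = beta, se = sqrt(diag(vc)),
                 residuals = res, fitted = fitted, sigma = sqrt(sigma2),
                 vcov = vc, df.residual = dfres, elements = d$elements,
                 weights = w, stats = solv_stats(-res)),
            class = "solv_fit")
}

#' @export
print.solv_fit <- function(x, ...) {
  cat("Correction-term weighted least-squares fit\n")
  cat(sprintf("  %d residual df, sigma = %.4f kcal/mol\n", x$df.residual,
              x$sigma))
  print(round(rbind(estimate = x$coefficients, se = x$se), 5))
  invisible(x)
}

#' @export
summary.solv_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$coefficients / object$se)
  out <- list(coefficients = tab, sigma = object$sigma,
              df.residual = object$df.residual, stats = object$stats)
  class(out) <- "summary.solv_fit"
  out
}

#' @export
print.summary.solv_fit <- function(x, ...) {
  cat("Weighted least-squares fit of the correction parameters\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual sigma %.4f on %d df; MSE %.4f, MAE %.4f, SD %.4f kcal/mol\n",
              x$sigma, x$df.residual, x$stats[["mse"]], x$stats[["mae"]],
              x$stats[["sd"]]))
  invisible(x)
}

#' @export
coef.solv_fit <- function(object, ...) object$coefficients

#' @export
residuals.solv_fit <- function(object, ...) object$residuals

#' @export
vcov.solv_fit <- function(object, ...) object$vcov

#' Predict solvation free energies from a fitted correction
#'
#' Applies the fitted linear correction to new feature rows and adds back
#' their electrostatic energies, giving predicted total solvation free
#' energies in kcal/mol.
#'
#' @param object A \code{\link{solv_fit}}.
#' @param newdata Feature rows as in \code{\link{assemble_design_matrix}}.
#' @param ... Unused.
#' @export
predict.solv_fit <- function(object, newdata, ...) {
  d <- assemble_design_matrix(newdata)
  nm <- names(object$coefficients)
  if (!all(nm %in% colnames(d$X)))
    stop("newdata lacks feature columns for: ",
         paste(setdiff(nm, colnames(d$X)), collapse = ", "))
  newdata$e_elst + as.vector(d$X[, nm, drop = FALSE] %*% object$coefficients)
}

#' Fit the per-solvent surface shift
#'
#' Given residuals \code{dg_ref - dg_model} for the solutes of one solvent
#' and their total cavity areas, the optimal shift is the closed-form
#' one-parameter least-squares solution
#' \deqn{\xi = \sum_i r_i S_i / \sum_i S_i^2.}
#'
#' @param residuals Numeric vector of residuals, kcal/mol.
#' @param total_areas Matching total cavity areas, Angstrom^2.
#' @return \code{xi} in kcal/(mol A^2).
#' @export
fit_xi_solv <- function(residuals, total_areas) {
  if (length(residuals) < 2)
    stop("need at least two solutes to fit a solvent shift")
  if (length(residuals) != length(total_areas))
    stop("residuals and areas differ in length")
  sum(residuals * total_areas) / sum(total_areas^2)
}

#' Error statistics: MSE, MAE and SD
#'
#' Summarizes signed errors \code{dg_calc - dg_ref}: the mean signed error
#' (MSE), the mean absolute error (MAE), and the standard deviation (SD),
#' the latter in its root-mean-square-error sense
#' \eqn{\sqrt{\mathrm{mean}(e^2)}}.
#'
#' @param errors Nonempty numeric vector of signed errors, kcal/mol.
#' @return Named numeric vector \code{c(mse, mae, sd)}.
#' @examples
#' solv_stats(c(1, -1))  # mse 0, mae 1, sd 1
#' @export
solv_stats <- function(errors) {
  if (!length(errors)) stop("empty error list")
  if (any(!is.finite(errors))) stop("non-finite errors")
  c(mse = mean(errors), mae = mean(abs(errors)),
    sd = sqrt(mean(errors^2)))
}

#' Write / read a training table as CSV
#'
#' The header is the column schema of
#' \code{\link{assemble_design_matrix}}: identifier columns (\code{id},
#' \code{solvent}, \code{subset}, \code{charge_state}), the reference
#' \code{dg_ref}, \code{e_elst}, \code{volume}, \code{weight} and the
#' per-element \code{S_<el>} / \code{q_<el>} feature columns.
#'
#' @param rows Training data frame.
#' @param file CSV path.
#' @export
write_training <- function(rows, file) {
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_training
#' @export
read_training <- function(file) {
  utils::read.csv(file, check.names = FALSE)
}
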