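# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.batman_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 std.error = unname(x$se))
}

#' @export
glance.batman_fit <- function(x, ...) {
  tibble::tibble(model = x$model, sse = x$sse, converged = x$converged,
                 a = x$a, b = x$b, de_generations = x$de_generations,
                 nobs = nrow(x$data))
}

#' @export
tidy.eyring_fit <- function(x, ...) {
  tibble::tibble(term = c("dH", "dS", "dG_ref"),
                 estimate = c(x$dH, x$dS, x$dG_ref),
                 std.error = c(x$se_dH, x$se_dS, x$se_dG))
}

#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(term = c("Ea", "lnA"), estimate = c(x$Ea, x$lnA),
                 std.error = c(x$se_Ea, x$se_lnA))
}

#' @export
tidy.phase_mem <- function(x, ...) {
  fe <- lme4::fixef(x$fit)
  tibble::tibble(term = names(fe), estimate = unname(fe),
                 std.error = unname(x$se_beta[names(fe)]))
}

#' @export
glance.phase_mem <- function(x, ...) {
  tibble::tibble(REML = as.numeric(stats::logLik(x$fit)),
                 sigma = stats::sigma(x$fit),
                 nobs = stats::nobs(x$fit),
                 singular = lme4::isSingular(x$fit, tol = 1e-6))
}

#' @export
tidy.eb_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 std.error = unname(x$se))
}

#' @export
glance.eb_fit <- function(x, ...) {
  tibble::tibble(nlp = x$value, n_par = length(x$estimate),
                 converged = x$converged, Tc = x$Tc,
                 rmse_median = stats::median(x$runs$rmse))
}

#' @export
tidy.cd_fit <- function(x, ...) {
  tibble::tibble(term = c("theta0", "k_rac", "delay"),
                 estimate = c(x$theta0, x$k_rac, x$delay),
                 std.error = c(x$se_theta0, x$se_k, x$se_delay))
}

#' @export
tidy.overload_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("Q_tot", "rho", "b_ns", "b_s1", "b_s2"),
                 estimate = c(p$Q_tot, p$rho, p$b_ns, p$b_s1, p$b_s2),
                 std.error = c(NA, x$se_rho, NA, NA, NA))
}
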