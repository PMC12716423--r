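# Maximum-likelihood estimation of model rates.

#' Fit compound-state model rates by maximum likelihood
#'
#' Optimizes the chosen rate parameters on the log scale with `optim`
#' (L-BFGS-B), holding all other parameters at their values in `params`.
#' Intended for moderate problems (parameter-recovery studies, profile
#' checks); full Bayesian treatment of the posterior is out of scope.
#'
#' @param tree,tips data as in [classe_loglik()].
#' @param space the `state_space`.
#' @param params starting [classe_parameters()]; also supplies the fixed
#'   parameters.
#' @param free character vector of parameter names to estimate, any of
#'   `"lambda_within"`, `"lambda_between"`, `"dispersal"`, `"biome_rate"`,
#'   `"extirpation"` (default `"lambda_within"`).
#' @param condition_on_survival,root passed to [classe_loglik()].
#' @param rtol,atol ODE tolerances (a slightly loose default speeds up the
#'   many likelihood evaluations of the optimizer).
#' @param control passed to [stats::optim()].
#' @return list with `params` (fitted `classe_parameters`), `loglik`,
#'   `convergence`, and the raw `optim` fit.
#' @export
fit_classe <- function(tree, tips, space, params, free = "lambda_within",
                       condition_on_survival = TRUE, root = "fitzjohn",
                       rtol = 1e-7, atol = 1e-9, control = list()) {
  stopifnot(inherits(params, "classe_parameters"))
  free <- match.arg(free, c("lambda_within", "lambda_between", "dispersal",
                            "biome_rate", "extirpation"), several.ok = TRUE)
  lens <- vapply(params[free], length, integer(1))
  unpack <- function(x) {
    p <- params
    at <- 0L
    for (f in free) {
      p[[f]] <- exp(x[at + seq_len(lens[[f]])])
      at <- at + lens[[f]]
    }
    p
  }
  negll <- function(x) {
    p <- unpack(x)
    gen <- build_generators(p, space)
    ll <- tryCatch(
      classe_loglik(tree, tips, gen, sampling_fraction = p$sampling_fraction,
                    condition_on_survival = condition_on_survival, root = root,
                    rtol = rtol, atol = atol),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  x0 <- log(pmax(unlist(params[free]), 1e-6))
  ctl <- utils::modifyList(list(maxit = 200), control)
  fit <- stats::optim(x0, negll, method = "L-BFGS-B",
                      lower = log(1e-6), upper = log(10), control = ctl)
  list(params = unpack(fit$par), loglik = -fit$value,
       convergence = fit$convergence, fit = fit)
}
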