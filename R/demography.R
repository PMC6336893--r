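#' Expected folded joint SFS under the split model
#'
#' Monte-Carlo coalescent expectation: the mean branch length subtending
#' each (i, j) sample configuration is accumulated over replicate
#' genealogies and scaled so the entries are expected site counts per unit
#' theta (theta = 4*Na*mu*L): E[sites in cell] = theta * E1. Folded and
#' masked like an observed joint spectrum. Total mass therefore scales
#' linearly in theta.
#'
#' @param params a [demographic_params()] (only the relative parameters
#'   matter here).
#' @param n1,n2 haploid sample sizes.
#' @param n_reps Monte-Carlo replicates (>= 1e4 recommended for fitting).
#' @param seed RNG seed; fixed seed gives a deterministic surface (common
#'   random numbers across optimizer evaluations).
#' @return A `norpop_jsfs` of expected (fractional) counts at theta = 1.
#' @export
expected_joint_sfs <- function(params, n1, n2, n_reps = 2e4, seed = 1) {
  b <- .cpp_expected_joint_branchlen(n1, n2, params$nua, params$Ta,
                                     params$Td, params$nu1F, params$nu2Y,
                                     n_reps, seed)
  joint_sfs(b / 2, n1, n2, folded = FALSE)
}

expected_ll_factory <- function(obs, mask, n1, n2, n_reps, seed,
                                likelihood) {
  keep <- !mask & obs >= 0
  function(p) {
    if (any(p[c(1, 4, 5)] <= 0) || p[3] < 0 || p[2] <= p[3]) return(-Inf)
    b <- .cpp_expected_joint_branchlen(n1, n2, p[1], p[2], p[3], p[4], p[5],
                                       n_reps, seed)
    e1 <- fold_joint_matrix(b / 2, n1, n2)
    tot <- sum(e1[keep])
    if (!is.finite(tot) || tot <= 0) return(-Inf)
    nz <- keep & obs > 0
    if (any(e1[nz] <= 0)) return(-Inf)
    if (likelihood == "multinomial") {
      sum(obs[nz] * log(e1[nz] / tot))
    } else {
      theta <- sum(obs[keep]) / tot
      sum(obs[nz] * log(theta * e1[nz])) - theta * tot
    }
  }
}

#' Fit the ancestral-change-plus-split model to a folded joint SFS
#'
#' Maximum composite likelihood over (nua, Ta, Td, nu1F, nu2Y): the
#' multinomial likelihood of the observed folded class proportions against
#' the normalized Monte-Carlo expected spectrum (theta profiles out;
#' a Poisson likelihood with theta profiled analytically is available by
#' flag and has the same optimum). Nelder-Mead from `n_starts` random
#' starting points on log scale (with Ta reparameterized as Td + dT to keep
#' Ta > Td), followed by a polish at a larger Monte-Carlo size. Standard
#' errors come from the expected Fisher information at the MLE in its
#' Gauss-Newton form for multinomial data (first derivatives of the folded
#' cell probabilities by central differences, positive semidefinite by
#' construction).
#'
#' @param jsfs observed folded joint SFS (`norpop_jsfs`).
#' @param mu mutation rate per generation per site.
#' @param g generation time in years.
#' @param l_eff effective sequence length (defaults to `jsfs$l_eff`).
#' @param init_box list of `c(lower, upper)` ranges for nua, dT (= Ta - Td),
#'   Td, nu1F, nu2Y starting values.
#' @param n_starts number of random starts.
#' @param seed seed for starts and for the common-random-number Monte-Carlo
#'   expectation.
#' @param n_reps,n_reps_final,n_reps_hessian Monte-Carlo sizes for search,
#'   polish, and Fisher-information/theta evaluation.
#' @param likelihood `"multinomial"` (default) or `"poisson"`.
#' @param hessian_step relative central-difference step for the cell
#'   probability derivatives.
#' @return An object of class `demographic_fit`: MLE, log composite
#'   likelihood, SEs, 95% CIs, fitted theta, reference size `Na` and
#'   physical-unit conversions.
#' @export
fit_demography <- function(jsfs, mu = 1.1e-8, g = 5, l_eff = jsfs$l_eff,
                           init_box = list(nua = c(0.5, 4), dT = c(0.05, 0.8),
                                           Td = c(0.01, 0.2),
                                           nu1F = c(0.3, 3), nu2Y = c(0.3, 3)),
                           n_starts = 3, seed = 1, n_reps = 2e4,
                           n_reps_final = 2e5, n_reps_hessian = 1e6,
                           likelihood = c("multinomial", "poisson"),
                           hessian_step = 0.02) {
  likelihood <- match.arg(likelihood)
  obs <- jsfs$matrix; mask <- jsfs$mask
  n1 <- jsfs$n1; n2 <- jsfs$n2
  mc_seed <- (seed * 2654435761) %% 2147483647
  ll_search <- expected_ll_factory(obs, mask, n1, n2, n_reps, mc_seed,
                                   likelihood)
  # z = log(nua, dT, Td, nu1F, nu2Y); Ta = Td + dT keeps the ordering
  unpack <- function(z) {
    e <- unname(exp(z))
    c(nua = e[1], Ta = e[2] + e[3], Td = e[3], nu1F = e[4], nu2Y = e[5])
  }
  obj <- function(z, llf) -llf(unpack(z))
  set.seed(seed)
  starts <- replicate(n_starts, vapply(init_box, function(b)
    log(runif(1, b[1], b[2])), numeric(1)))
  fits <- lapply(seq_len(n_starts), function(i) {
    tryCatch(optim(starts[, i], obj, llf = ll_search, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(fits) == 0)
    stop("no start converged; starts tried:\n",
         paste(capture_starts(starts), collapse = "\n"))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  ll_final <- expected_ll_factory(obs, mask, n1, n2, n_reps_final, mc_seed,
                                  likelihood)
  best <- optim(best$par, obj, llf = ll_final, method = "Nelder-Mead",
                control = list(maxit = 300, reltol = 1e-10))
  mle <- unpack(best$par)

  # expected Fisher information via the Gauss-Newton form for multinomial
  # data: I_ij = S * sum_k (dp_k/dtheta_i)(dp_k/dtheta_j) / p_k with cell
  # probabilities from the Monte-Carlo expected spectrum (common random
  # numbers) and first derivatives by central differences. Positive
  # semidefinite by construction, unlike a noisy numerical Hessian.
  keep <- !mask
  probs_at <- function(p) {
    b <- .cpp_expected_joint_branchlen(n1, n2, p[1], p[2], p[3], p[4], p[5],
                                       n_reps_hessian, mc_seed)
    e1 <- fold_joint_matrix(b / 2, n1, n2)
    list(p = e1[keep] / sum(e1[keep]), e1sum = sum(e1[keep]))
  }
  at_mle <- probs_at(mle)
  S_obs <- sum(obs[keep])
  J <- vapply(seq_along(mle), function(i) {
    h <- hessian_step * mle[i]
    up <- mle; dn <- mle
    up[i] <- mle[i] + h; dn[i] <- mle[i] - h
    (probs_at(up)$p - probs_at(dn)$p) / (2 * h)
  }, numeric(sum(keep)))
  I <- S_obs * crossprod(J / sqrt(at_mle$p))
  se <- rep(NA_real_, 5)
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (!is.null(V) && all(diag(V) > 0)) se <- sqrt(diag(V))
  else warning("Fisher information is singular; SEs unavailable")
  names(se) <- names(mle)
  ci <- rbind(lower = mle - 1.96 * se, upper = mle + 1.96 * se)

  # fitted composite theta: observed segregating sites over the expected
  # spectrum mass at the MLE (theta = 4*Na*mu*L)
  theta_hat <- S_obs / at_mle$e1sum
  Na <- if (is.finite(l_eff)) na_from_theta(theta_hat, mu, l_eff)
        else NA_real_
  structure(list(par = mle, loglik = -best$value, se = se, ci = ci,
                 theta_hat = theta_hat, Na = Na, mu = mu, g = g,
                 l_eff = l_eff,
                 physical = if (is.finite(Na))
                   to_physical_units(mle, Na, g) else NULL,
                 convergence = best$convergence,
                 n_reps = c(search = n_reps, final = n_reps_final,
                            hessian = n_reps_hessian),
                 seed = seed),
            class = "demographic_fit")
}

capture_starts <- function(starts) {
  apply(starts, 2, function(z) paste(signif(exp(z), 3), collapse = ", "))
}

#' @export
print.demographic_fit <- function(x, ...) {
  cat("demographic fit (log composite likelihood ", signif(x$loglik, 8),
      ")\n", sep = "")
  tab <- rbind(MLE = x$par, SE = x$se, x$ci)
  print(signif(tab, 4))
  cat(sprintf("theta_hat = %.4g; Na = %s diploids\n", x$theta_hat,
              format(round(x$Na), big.mark = ",")))
  if (!is.null(x$physical)) {
    cat(sprintf("split %s years ago; ancestral change %s years ago\n",
                format(round(x$physical$years["Td"]), big.mark = ","),
                format(round(x$physical$years["Ta"]), big.mark = ",")))
  }
  invisible(x)
}

#' Reference ancestral size from fitted theta
#'
#' Na = theta / (4 * mu * L), with theta the observed number of segregating
#' sites divided by the sum of the expected spectrum at the best fit.
#'
#' @param theta_hat fitted composite theta (dimensionless count scale).
#' @param mu mutation rate per generation per site.
#' @param L effective sequence length in bp.
#' @return Na in diploid individuals.
#' @export
na_from_theta <- function(theta_hat, mu, L) {
  if (any(c(theta_hat, mu, L) <= 0)) stop("all inputs must be > 0")
  theta_hat / (4 * mu * L)
}

#' Convert relative demographic parameters to physical units
#'
#' Sizes in individuals: nu * Na. Times in years: T * 2 * Na * g.
#'
#' @param par named vector with nua, Ta, Td, nu1F, nu2Y (a fit's `par`).
#' @param Na reference ancestral size in diploids.
#' @param g generation time in years.
#' @return List with `sizes` (individuals) and `years`.
#' @export
to_physical_units <- function(par, Na, g) {
  list(sizes = c(Na = Na, ancestral = par[["nua"]] * Na,
                 pop1 = par[["nu1F"]] * Na, pop2 = par[["nu2Y"]] * Na),
       years = c(Ta = par[["Ta"]] * 2 * Na * g,
                 Td = par[["Td"]] * 2 * Na * g))
}
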