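#' Fit the non-phylogenetic binomial mixture model
#'
#' Treats genomes as independent so that gene-family presence/absence
#' follows a two-component binomial mixture: a *non-essential* component in
#' which a family is present with probability `pi_p` in each parasite
#' genome and `pi_q` in each non-parasite genome, and an *essential*
#' component with a single presence probability `pi_r` in every genome.
#' With `sP`, `sN` the presence counts of family `g` among the `nP`
#' parasites and `nN` non-parasites (`s = sP + sN`, `n = nP + nN`), the
#' log-likelihood is
#' `sum_g ln[ alpha pi_p^sP (1-pi_p)^(nP-sP) pi_q^sN (1-pi_q)^(nN-sN)
#'          + (1-alpha) pi_r^s (1-pi_r)^(n-s) ]`,
#' maximized by EM. Families are collapsed to their `(sP, sN)`
#' sufficient-statistic classes, so the cost per iteration is independent
#' of the number of families. The mixture is structurally asymmetric (only
#' one component distinguishes parasites), so there is no label-switching
#' ambiguity.
#'
#' @param matrix a [pa_matrix].
#' @param annotation named logical vector over the taxa of `matrix`
#'   (`TRUE` = parasite), e.g. from [taxon_annotation()]; needs at least
#'   one `TRUE` and one `FALSE`.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param restarts number of random initializations (the best fit is
#'   returned).
#' @param seed integer seed for the initializations.
#' @param condition_observable logical; if `TRUE`, each family likelihood
#'   is divided by `1 - P(all absent)` for its component (truncation
#'   correction for databases that cannot contain all-absent families).
#'   Off by default.
#' @return an object of class `binom_mixture` with components `alpha`,
#'   `pi_p`, `pi_q`, `pi_r`, `loglik`, `loglik_trace`, `tau` (posterior
#'   probability of the non-essential component per family), `iterations`,
#'   `converged`, `boundary`, `identified` (`FALSE` when the mixture fits
#'   no better than a single binomial component, leaving `alpha`
#'   unidentified), `n_parasite`, `n_nonparasite`.
#' @seealso [assign_categories()], [partitioned_distances()]
#' @export
fit_binomial_mixture <- function(matrix, annotation, max_iter = 2000L,
                                 tol = 1e-8, restarts = 5L, seed = 1L,
                                 condition_observable = FALSE) {
  annotation <- annotation[rownames(matrix)]
  if (anyNA(annotation) || !any(annotation) || !any(!annotation)) {
    stop2("mix_annotation_error",
          "annotation must flag >= 1 parasite and >= 1 non-parasite taxon")
  }
  nP <- sum(annotation); nN <- sum(!annotation)
  sP <- colSums(matrix[annotation, , drop = FALSE])
  sN <- colSums(matrix[!annotation, , drop = FALSE])
  key <- paste(sP, sN)
  classes <- !duplicated(key)
  cls_sP <- sP[classes]; cls_sN <- sN[classes]
  cls_w <- as.vector(table(factor(key, levels = key[classes])))
  degenerate <- length(cls_w) == 1L
  comp_loglik <- function(par) {
    # rows: per class; returns cbind(log L_N, log L_E)
    lN <- cls_sP * log(par$pi_p) + (nP - cls_sP) * log1p(-par$pi_p) +
      cls_sN * log(par$pi_q) + (nN - cls_sN) * log1p(-par$pi_q)
    lE <- (cls_sP + cls_sN) * log(par$pi_r) +
      (nP + nN - cls_sP - cls_sN) * log1p(-par$pi_r)
    if (condition_observable) {
      lN <- lN - log1p(-exp(nP * log1p(-par$pi_p) + nN * log1p(-par$pi_q)))
      lE <- lE - log1p(-exp((nP + nN) * log1p(-par$pi_r)))
    }
    cbind(lN, lE)
  }
  run_em <- function(par) {
    ll_trace <- numeric(0L)
    ll_old <- -Inf
    iter <- 0L
    tau <- NULL
    repeat {
      iter <- iter + 1L
      l <- comp_loglik(par)
      a <- log(par$alpha) + l[, 1L]
      b <- log1p(-par$alpha) + l[, 2L]
      mx <- pmax(a, b)
      ll <- sum(cls_w * (mx + log(exp(a - mx) + exp(b - mx))))
      ll_trace <- c(ll_trace, ll)
      tau <- 1 / (1 + exp(b - a))
      if (!is.finite(ll) || abs(ll - ll_old) < tol || iter >= max_iter) break
      ll_old <- ll
      wt <- cls_w * tau
      swt <- sum(wt)
      par$alpha <- clamp01(swt / sum(cls_w))
      par$pi_p <- clamp01(sum(wt * cls_sP) / (nP * swt))
      par$pi_q <- clamp01(sum(wt * cls_sN) / (nN * swt))
      par$pi_r <- clamp01(sum(cls_w * (1 - tau) * (cls_sP + cls_sN)) /
                            ((nP + nN) * sum(cls_w * (1 - tau))))
    }
    list(par = par, loglik = ll_trace[length(ll_trace)],
         loglik_trace = ll_trace, tau = tau, iterations = iter,
         converged = is.finite(ll_trace[length(ll_trace)]) &&
           iter < max_iter && !degenerate)
  }
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(i) {
      if (i == 1L) {
        # moment-flavoured start: split families at the median presence
        list(alpha = 0.5,
             pi_p = clamp01(mean(sP[sP + sN <= stats::median(sP + sN)]) / nP),
             pi_q = clamp01(mean(sN[sP + sN <= stats::median(sP + sN)]) / nN),
             pi_r = clamp01(mean((sP + sN)[sP + sN > stats::median(sP + sN)]) /
                              (nP + nN)))
      } else {
        list(alpha = stats::runif(1, 0.1, 0.9),
             pi_p = stats::runif(1, 0.01, 0.5), pi_q = stats::runif(1, 0.05, 0.95),
             pi_r = stats::runif(1, 0.05, 0.95))
      }
    })
  })
  fits <- lapply(starts, run_em)
  lls <- vapply(fits, `[[`, numeric(1L), "loglik")
  lls[!is.finite(lls)] <- -Inf
  best <- fits[[which.max(lls)]]
  eps <- 1e-5
  boundary <- with(best$par, any(c(alpha, pi_p, pi_q, pi_r) < eps |
                                   c(alpha, pi_p, pi_q, pi_r) > 1 - eps))
  # identifiability: when the data support only one component the
  # likelihood surface is a flat ridge in alpha (tau = alpha is an EM
  # fixed point), so compare against the best single-component model
  p_hat <- sum(cls_w * (cls_sP + cls_sN)) / (sum(cls_w) * (nP + nN))
  ll_single <- binomial_mixture_loglik(
    matrix, annotation, alpha = 1e-12, pi_p = 0.5, pi_q = 0.5,
    pi_r = clamp01(p_hat), condition_observable = condition_observable)
  identified <- (best$loglik - ll_single) > stats::qchisq(0.95, 3) / 2
  if (!identified) {
    warning("mixture fits no better than a single component; ",
            "alpha is not identified")
  }
  if (degenerate) {
    warning("all families share one (sP, sN) class; mixture is degenerate")
  }
  tau_fam <- stats::setNames(best$tau[match(key, key[classes])],
                             colnames(matrix))
  structure(list(alpha = best$par$alpha, pi_p = best$par$pi_p,
                 pi_q = best$par$pi_q, pi_r = best$par$pi_r,
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 tau = tau_fam, iterations = best$iterations,
                 converged = best$converged, boundary = boundary,
                 identified = identified,
                 n_parasite = nP, n_nonparasite = nN,
                 condition_observable = condition_observable,
                 n_families = ncol(matrix)),
            class = "binom_mixture")
}

clamp01 <- function(x, eps = 1e-9) {
  if (!is.finite(x)) return(0.5)
  min(max(x, eps), 1 - eps)
}

#' Evaluate the binomial-mixture log-likelihood at given parameters
#'
#' Direct evaluation of the mixture formula (no fitting); used both
#' internally and as an oracle target.
#'
#' @inheritParams fit_binomial_mixture
#' @param alpha,pi_p,pi_q,pi_r mixture parameters.
#' @return the log-likelihood (a number).
#' @export
binomial_mixture_loglik <- function(matrix, annotation, alpha, pi_p, pi_q,
                                    pi_r, condition_observable = FALSE) {
  annotation <- annotation[rownames(matrix)]
  nP <- sum(annotation); nN <- sum(!annotation)
  sP <- colSums(matrix[annotation, , drop = FALSE])
  sN <- colSums(matrix[!annotation, , drop = FALSE])
  lN <- sP * log(pi_p) + (nP - sP) * log1p(-pi_p) +
    sN * log(pi_q) + (nN - sN) * log1p(-pi_q)
  lE <- (sP + sN) * log(pi_r) + (nP + nN - sP - sN) * log1p(-pi_r)
  if (condition_observable) {
    lN <- lN - log1p(-exp(nP * log1p(-pi_p) + nN * log1p(-pi_q)))
    lE <- lE - log1p(-exp((nP + nN) * log1p(-pi_r)))
  }
  a <- log(alpha) + lN
  b <- log1p(-alpha) + lE
  mx <- pmax(a, b)
  sum(mx + log(exp(a - mx) + exp(b - mx)))
}

#' @export
print.binom_mixture <- function(x, ...) {
  cat("Non-phylogenetic binomial mixture\n")
  cat(sprintf("  alpha (non-essential fraction) = %.4f\n", x$alpha))
  cat(sprintf("  pi_p (non-essential, parasite) = %.4f\n", x$pi_p))
  cat(sprintf("  pi_q (non-essential, non-parasite) = %.4f\n", x$pi_q))
  cat(sprintf("  pi_r (essential, all genomes) = %.4f\n", x$pi_r))
  cat(sprintf("  log-likelihood %.3f after %d EM iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (x$boundary) cat("  warning: fit on the parameter boundary\n")
  if (!x$identified) {
    cat("  warning: no better than a single component; alpha not identified\n")
  }
  invisible(x)
}

#' @export
summary.binom_mixture <- function(object, ...) {
  print(object)
  cat(sprintf("  %d families over %d parasite + %d non-parasite genomes\n",
              object$n_families, object$n_parasite, object$n_nonparasite))
  q <- stats::quantile(object$tau, c(0, .25, .5, .75, 1))
  cat("  posterior P(non-essential) quantiles:\n")
  print(round(q, 4))
  invisible(object)
}

#' @export
coef.binom_mixture <- function(object, ...) {
  c(alpha = object$alpha, pi_p = object$pi_p, pi_q = object$pi_q,
    pi_r = object$pi_r)
}

#' @export
logLik.binom_mixture <- function(object, ...) {
  structure(object$loglik, df = 4L, class = "logLik")
}

#' Posterior non-essential probabilities for new or fitted families
#'
#' @param object a `binom_mixture`.
#' @param newdata optional [pa_matrix] of additional families; when
#'   omitted the fitted per-family posteriors are returned.
#' @param annotation named logical parasite flags over the taxa of
#'   `newdata` (required with `newdata`).
#' @param ... unused.
#' @return named vector of posterior probabilities that each family
#'   belongs to the non-essential component.
#' @export
predict.binom_mixture <- function(object, newdata = NULL,
                                  annotation = NULL, ...) {
  if (is.null(newdata)) return(object$tau)
  if (is.null(annotation)) {
    stop2("mix_annotation_error", "annotation is required with newdata")
  }
  annotation <- annotation[rownames(newdata)]
  sP <- colSums(newdata[annotation, , drop = FALSE])
  sN <- colSums(newdata[!annotation, , drop = FALSE])
  nP <- sum(annotation); nN <- sum(!annotation)
  lN <- sP * log(object$pi_p) + (nP - sP) * log1p(-object$pi_p) +
    sN * log(object$pi_q) + (nN - sN) * log1p(-object$pi_q)
  lE <- (sP + sN) * log(object$pi_r) +
    (nP + nN - sP - sN) * log1p(-object$pi_r)
  if (object$condition_observable) {
    lN <- lN - log1p(-exp(nP * log1p(-object$pi_p) +
                            nN * log1p(-object$pi_q)))
    lE <- lE - log1p(-exp((nP + nN) * log1p(-object$pi_r)))
  }
  a <- log(object$alpha) + lN
  b <- log1p(-object$alpha) + lE
  stats::setNames(1 / (1 + exp(b - a)), colnames(newdata))
}

#' Empirical-Bayes assignment of families to categories
#'
#' @param fit a `binom_mixture` (or any object with a `tau` component of
#'   per-family posterior probabilities of being non-essential).
#' @param threshold posterior threshold; a family is `non_essential` iff
#'   `tau >= threshold` (ties go to non-essential).
#' @return named character vector over families with values
#'   `"essential"` / `"non_essential"`.
#' @export
assign_categories <- function(fit, threshold = 0.5) {
  stats::setNames(ifelse(fit$tau >= threshold, "non_essential", "essential"),
                  names(fit$tau))
}

#' Per-category conditioned logdet distances, combined
#'
#' Runs the conditioned logdet pipeline separately on each category's
#' column subset and combines the per-category matrices by a weighted sum:
#' by default per-pair inverse-variance weights
#' (`V(x,y) = 1 / sum_k 1/V_k(x,y)`), alternatively fixed proportional
#' weights `w_k = |category k| / G`.
#'
#' Categories with fewer than 4 families present in at least one genome are
#' excluded with a warning; if only one usable category remains the result
#' degrades to the single-category pipeline.
#'
#' @param matrix a [pa_matrix].
#' @param assignment named character vector over families (category
#'   labels), e.g. from [assign_categories()].
#' @param weights `"inverse_variance"` (default) or `"proportions"`.
#' @param repair,beta,delta passed to [conditioned_distance_set()].
#' @return a `combined_dist` (with a `categories` attribute listing the
#'   categories used).
#' @export
partitioned_distances <- function(matrix, assignment,
                                  weights = c("inverse_variance",
                                              "proportions"),
                                  repair = "on_failure", beta = 0.5,
                                  delta = 1e-6) {
  weights <- match.arg(weights)
  assignment <- assignment[colnames(matrix)]
  cats <- split(colnames(matrix), assignment)
  usable <- list()
  for (k in names(cats)) {
    sub <- matrix[, cats[[k]], drop = FALSE]
    if (sum(colSums(sub) > 0L) < 4L) {
      warning(sprintf(
        "category '%s' has < 4 families present in some genome; excluded", k))
      next
    }
    usable[[k]] <- sub
  }
  if (length(usable) == 0L) {
    stop2("mix_partition_error", "no usable category")
  }
  if (length(usable) == 1L) {
    warning("only one usable category; running the single-category pipeline")
  }
  parts <- lapply(usable, function(sub) {
    combine_matrices(conditioned_distance_set(sub, repair = repair,
                                              beta = beta, delta = delta),
                     taxa = rownames(matrix))
  })
  out <- pool_combined(parts, weights = weights,
                       sizes = vapply(usable, ncol, integer(1L)),
                       G = ncol(matrix))
  attr(out, "categories") <- names(usable)
  out
}

# Pool a list of combined_dist objects over one taxon set.
pool_combined <- function(parts, weights, sizes, G) {
  taxa <- parts[[1L]]$taxa
  p <- length(taxa)
  if (weights == "inverse_variance") {
    SW <- base::matrix(0, p, p, dimnames = list(taxa, taxa)); W <- SW
    for (m in parts) {
      w <- 1 / m$V
      diag(w) <- 0
      SW <- SW + m$D * w
      W <- W + w
    }
    D <- SW / W; V <- 1 / W
  } else {
    wk <- sizes / G
    wk <- wk / sum(wk)   # renormalize over the categories actually used
    D <- base::matrix(0, p, p, dimnames = list(taxa, taxa)); V <- D
    for (i in seq_along(parts)) {
      D <- D + wk[i] * parts[[i]]$D
      V <- V + wk[i]^2 * parts[[i]]$V
    }
  }
  diag(D) <- 0; diag(V) <- 0
  K <- Reduce(`+`, lapply(parts, `[[`, "contributors"))
  structure(list(taxa = taxa, D = D, V = V, contributors = K),
            class = "combined_dist")
}
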