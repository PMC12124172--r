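#' Drop one of each pair of highly correlated covariate layers
#'
#' Computes pairwise correlations (Spearman by default) over cells that are
#' non-nodata in every layer and iteratively removes layers until no
#' retained pair has |r| above the threshold. From a violating pair the
#' layer with the larger mean absolute correlation to all other retained
#' layers is dropped (ties by layer-name order), keeping the more
#' independent layer. Constant layers (undefined correlation) are dropped
#' up front with a warning.
#'
#' @param stack named list of co-registered `raster_grid` layers.
#' @param threshold correlation magnitude above which a pair violates
#'   (default 0.7).
#' @param method "spearman" (default), "pearson" or "kendall".
#' @return list: `stack` (retained layers), `report` (data.frame of drops:
#'   dropped, kept, r, reason).
#' @export
prune_correlated <- function(stack, threshold = 0.7,
                             method = c("spearman", "pearson", "kendall")) {
  method <- match.arg(method)
  check_coregistered(stack)
  report <- data.frame(dropped = character(0), kept = character(0),
                       r = numeric(0), reason = character(0))
  vals <- vapply(stack, function(g) as.vector(g$values),
                 numeric(length(stack[[1L]]$values)))
  ok <- stats::complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]
  keep <- names(stack)
  const <- vapply(keep, function(nm) stats::sd(vals[, nm]) == 0, TRUE)
  if (any(const)) {
    warning("dropping constant layer(s): ",
            paste(keep[const], collapse = ", "))
    report <- rbind(report, data.frame(dropped = keep[const], kept = NA,
                                       r = NA, reason = "constant"))
    keep <- keep[!const]
  }
  if (length(keep) >= 2L) repeat {
    cm <- stats::cor(vals[, keep, drop = FALSE], method = method)
    diag(cm) <- 0
    acm <- abs(cm)
    if (max(acm) <= threshold) break
    pair <- which(acm == max(acm), arr.ind = TRUE)[1L, ]
    a <- keep[pair[1L]]; b <- keep[pair[2L]]
    ma <- mean(acm[a, setdiff(keep, a)])
    mb <- mean(acm[b, setdiff(keep, b)])
    drop <- if (ma > mb) a else if (mb > ma) b else sort(c(a, b))[1L]
    kept <- setdiff(c(a, b), drop)
    report <- rbind(report, data.frame(dropped = drop, kept = kept,
                                       r = cm[a, b], reason = "correlated"))
    keep <- setdiff(keep, drop)
    if (length(keep) < 2L) break
  }
  list(stack = stack[keep], report = report)
}

#' Build the feature specification for a maxent-style model
#'
#' Features are linear and quadratic transforms of each covariate,
#' standardized by mean and sd computed over the background sample, so
#' standardized background features have mean 0 and sd 1.
#'
#' @param bg_covariates matrix of covariate values at background points.
#' @param transforms subset of c("linear", "quadratic").
#' @return a `feature_spec` with the constants needed to featurize any
#'   point set identically.
#' @export
feature_spec <- function(bg_covariates,
                         transforms = c("linear", "quadratic")) {
  transforms <- match.arg(transforms, several.ok = TRUE)
  raw <- featurize_raw(bg_covariates, transforms)
  m <- colMeans(raw); s <- apply(raw, 2L, stats::sd)
  drop <- !is.finite(s) | s == 0
  if (any(drop)) {
    warning("dropping constant feature(s): ",
            paste(colnames(raw)[drop], collapse = ", "))
  }
  structure(list(covariates = colnames(bg_covariates),
                 transforms = transforms,
                 feature_names = colnames(raw)[!drop],
                 mean = m[!drop], sd = s[!drop]),
            class = "feature_spec")
}

featurize_raw <- function(x, transforms) {
  x <- as.matrix(x)
  out <- NULL; nms <- character(0)
  if ("linear" %in% transforms) { out <- cbind(out, x); nms <- c(nms, colnames(x)) }
  if ("quadratic" %in% transforms) {
    out <- cbind(out, x^2); nms <- c(nms, paste0(colnames(x), "^2"))
  }
  colnames(out) <- nms
  out
}

#' Featurize covariates under a feature spec
#' @param spec a `feature_spec`.
#' @param covariates matrix with the spec's covariate columns.
#' @return standardized feature matrix.
#' @export
featurize <- function(spec, covariates) {
  covariates <- as.matrix(covariates)
  miss <- setdiff(spec$covariates, colnames(covariates))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "))
  raw <- featurize_raw(covariates[, spec$covariates, drop = FALSE],
                       spec$transforms)
  raw <- raw[, spec$feature_names, drop = FALSE]
  sweep(sweep(raw, 2L, spec$mean), 2L, spec$sd, "/")
}

#' Fit a presence-only maximum-entropy model
#'
#' Maximizes the L1-penalized maxent log-likelihood
#' `mean(F_p w) - log mean(exp(F_b w)) - beta * sum(lambda_j |w_j|)`
#' over presence features `F_p` and background features `F_b`, with
#' per-feature default penalties `lambda_j = sd_j(presence features) /
#' sqrt(n_presences)`. The optimizer is deterministic proximal gradient
#' (FISTA with backtracking) initialized at zero weights; convergence when
#' the generalized-gradient sup-norm drops below 1e-6 (else a warning after
#' 1e4 iterations). Species with fewer than 10 presences are refused
#' (recorded as unmodelled).
#'
#' @param presences data.frame with x, y of presence points.
#' @param background data.frame with x, y of background points (the
#'   target-group sample).
#' @param stack named list of covariate `raster_grid` layers.
#' @param beta regularization multiplier (> 0, default 1).
#' @param species label stored on the model.
#' @param transforms feature classes, c("linear", "quadratic").
#' @param max_iter,tol optimizer controls.
#' @return an `sdm_model`: weights, `beta`, `lambda`, feature spec,
#'   `log_partition` over background, convergence info. AUCs and the
#'   maxSSS threshold are filled by [tune_beta()] / downstream calls.
#' @export
fit_maxent <- function(presences, background, stack, beta = 1,
                       species = "species", transforms = c("linear", "quadratic"),
                       max_iter = 10000L, tol = 1e-6) {
  if (beta <= 0) stop("beta must be positive")
  if (nrow(presences) < 10L) {
    warning(sprintf("species '%s': fewer than 10 presences; not modelled", species))
    return(structure(list(species = species, unmodelled = TRUE),
                     class = "sdm_model"))
  }
  cov_p <- extract_stack_at(stack, presences$x, presences$y)
  cov_b <- extract_stack_at(stack, background$x, background$y)
  okp <- stats::complete.cases(cov_p); okb <- stats::complete.cases(cov_b)
  cov_p <- cov_p[okp, , drop = FALSE]; cov_b <- cov_b[okb, , drop = FALSE]
  spec <- feature_spec(cov_b, transforms)
  Fp <- featurize(spec, cov_p)
  Fb <- featurize(spec, cov_b)
  lambda <- apply(Fp, 2L, stats::sd) / sqrt(nrow(Fp))
  lambda[!is.finite(lambda)] <- 1 / sqrt(nrow(Fp))
  fit <- maxent_optimize(Fp, Fb, beta * lambda, max_iter, tol)
  bg_raw <- exp(as.vector(Fb %*% fit$w) - fit$logZ)
  structure(list(species = species, weights = fit$w, beta = beta,
                 lambda = lambda, feature_spec = spec,
                 log_partition = fit$logZ, background_raw = bg_raw,
                 converged = fit$converged, n_iter = fit$iter,
                 n_presences = nrow(Fp), n_background = nrow(Fb),
                 threshold_maxsss = NA_real_,
                 auc_train = NA_real_, auc_test = NA_real_,
                 unmodelled = FALSE),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  if (isTRUE(x$unmodelled)) {
    cat(sprintf("sdm_model '%s': unmodelled (too few presences)\n", x$species))
    return(invisible(x))
  }
  cat(sprintf("sdm_model '%s': %d features, beta %.3g, |w|_1 = %.4g%s\n",
              x$species, length(x$weights), x$beta, sum(abs(x$weights)),
              if (!x$converged) " [not converged]" else ""))
  if (is.finite(x$auc_train))
    cat(sprintf("  AUC train %.3f / test %.3f, maxSSS threshold %.4g\n",
                x$auc_train, x$auc_test, x$threshold_maxsss))
  invisible(x)
}

# negative penalized objective pieces -------------------------------------
maxent_smooth <- function(w, Fp, Fb) {
  s <- as.vector(Fb %*% w)
  M <- max(s)
  lse <- M + log(mean(exp(s - M)))
  -mean(as.vector(Fp %*% w)) + lse
}

maxent_grad <- function(w, Fp, Fb) {
  s <- as.vector(Fb %*% w)
  q <- exp(s - max(s)); q <- q / sum(q)
  -colMeans(Fp) + as.vector(crossprod(Fb, q))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

maxent_objective <- function(w, Fp, Fb, lam)
  maxent_smooth(w, Fp, Fb) + sum(lam * abs(w))

maxent_optimize <- function(Fp, Fb, lam, max_iter = 10000L, tol = 1e-6) {
  p <- ncol(Fp)
  w <- z <- rep(0, p)
  L <- 1; theta <- 1
  f_z <- maxent_smooth(z, Fp, Fb)
  for (it in seq_len(max_iter)) {
    g <- maxent_grad(z, Fp, Fb)
    repeat {
      w_new <- soft_threshold(z - g / L, lam / L)
      d <- w_new - z
      if (maxent_smooth(w_new, Fp, Fb) <=
          f_z + sum(g * d) + L / 2 * sum(d^2) + 1e-12) break
      L <- L * 2
      if (L > 1e12) break
    }
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    z <- w_new + (theta - 1) / theta_new * (w_new - w)
    w <- w_new; theta <- theta_new
    f_z <- maxent_smooth(z, Fp, Fb)
    # generalized gradient (optimality) check at w
    gw <- maxent_grad(w, Fp, Fb)
    opt <- ifelse(w != 0, abs(gw + lam * sign(w)), pmax(abs(gw) - lam, 0))
    if (max(opt) < tol) {
      s <- as.vector(Fb %*% w)
      return(list(w = w, logZ = max(s) + log(mean(exp(s - max(s)))),
                  converged = TRUE, iter = it))
    }
    L <- max(L / 2, 1e-3)
  }
  warning("maxent optimizer reached the iteration cap without convergence")
  s <- as.vector(Fb %*% w)
  list(w = w, logZ = max(s) + log(mean(exp(s - max(s)))),
       converged = FALSE, iter = max_iter)
}

#' Predict habitat suitability over a raster stack
#'
#' Per cell, the raw relative suitability is
#' `s = exp(w . f(x) - log_partition)` (mean 1 over background). The map is
#' passed through a logistic transform `c s / (1 + c s)` with `c` chosen so
#' the mean over the background sample equals the `prevalence` constant
#' (default 0.5). Monotone in the linear predictor; nodata propagates.
#'
#' @param model an `sdm_model`.
#' @param stack covariate layers (must contain the model covariates).
#' @param prevalence target mean suitability over background (0 < tau < 1).
#' @return `raster_grid` of suitability in \[0, 1\].
#' @export
predict_suitability <- function(model, stack, prevalence = 0.5) {
  if (isTRUE(model$unmodelled)) stop("cannot predict from an unmodelled species")
  check_coregistered(stack)
  template <- stack[[1L]]
  cc <- cell_centers(template)
  cov <- extract_stack_at(stack, cc$x, cc$y)
  ok <- stats::complete.cases(cov)
  s_raw <- rep(NA_real_, nrow(cov))
  Fc <- featurize(model$feature_spec, cov[ok, , drop = FALSE])
  s_raw[ok] <- exp(as.vector(Fc %*% model$weights) - model$log_partition)
  cscale <- logistic_scale(model, prevalence)
  out <- cscale * s_raw / (1 + cscale * s_raw)
  m <- matrix(out, nrow(template$values), ncol(template$values))
  raster_grid(m, template$origin_x, template$origin_y, template$cell_size,
              template$nodata, template$crs_tag)
}

# c solving mean over background of c s / (1 + c s) = prevalence.
# Background raw suitabilities have mean 1; with all-zero weights s == 1
# everywhere and c = tau / (1 - tau) gives the flat map at tau.
logistic_scale <- function(model, prevalence) {
  sb <- model$background_raw %||% 1
  if (length(sb) == 1L) return(prevalence / (1 - prevalence) / sb)
  f <- function(cc) mean(cc * sb / (1 + cc * sb)) - prevalence
  stats::uniroot(f, c(1e-12, 1e12), tol = 1e-12)$root
}

#' Score points under a fitted model (raw relative suitability)
#' @param model an `sdm_model`.
#' @param covariates matrix of covariate values at the points.
#' @return numeric scores `exp(w.f - logZ)`.
#' @export
score_points <- function(model, covariates) {
  Fm <- featurize(model$feature_spec, covariates)
  exp(as.vector(Fm %*% model$weights) - model$log_partition)
}

#' Area under the ROC curve for presence vs background scores
#'
#' `(concordant pairs + 0.5 ties) / (n_p * n_b)`, computed by sorted
#' counting; identical to the Mann-Whitney rank-sum formulation.
#'
#' @param scores_presence,scores_background non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("AUC is undefined for empty score sets")
  sb <- sort(scores_background)
  n_lt <- findInterval(scores_presence, sb, left.open = TRUE)  # b < s (strict)
  n_le <- findInterval(scores_presence, sb)                    # b <= s
  sum(n_lt + 0.5 * (n_le - n_lt)) /
    (length(scores_presence) * length(scores_background))
}

#' Threshold maximizing (sensitivity + specificity) / 2
#'
#' Candidates are all distinct observed scores; sensitivity is
#' `P(presence >= t)`, specificity `P(background < t)`. Ties break toward
#' the smallest threshold.
#'
#' @inheritParams evaluate_auc
#' @return the maxSSS threshold.
#' @export
threshold_maxsss <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("maxSSS is undefined for empty score sets")
  cand <- sort(unique(c(scores_presence, scores_background)))
  sp <- sort(scores_presence); sb <- sort(scores_background)
  np <- length(sp); nb <- length(sb)
  sens <- (np - findInterval(cand, sp, left.open = TRUE)) / np  # P(p >= t)
  spec <- findInterval(cand, sb, left.open = TRUE) / nb          # P(b < t)
  obj <- (sens + spec) / 2
  # floating-point-safe tie handling: scores within 1e-12 of the maximum
  # count as tied, and the smallest such threshold wins
  cand[which(obj >= max(obj) - 1e-12)[1L]]
}

#' Fit with overfitting control via the beta multiplier
#'
#' Splits presences into train/test (70/30 by default, fixed seed), fits at
#' `beta = 1`, and doubles beta (at most `max_doublings` times) while the
#' train-test AUC gap exceeds `overfit_gap`. The first model passing the
#' gap is returned, else the last fitted with `overfit_flag = TRUE`. Too
#' few presences to split falls back to a no-split fit, flagged.
#'
#' @inheritParams fit_maxent
#' @param split test fraction of presences in (0, 1).
#' @param overfit_gap maximum acceptable `auc_train - auc_test` (default
#'   0.05; any value in (0, 1\] may be supplied).
#' @param max_doublings cap on beta doublings.
#' @param seed seed for the presence partition.
#' @return an `sdm_model` with `auc_train`, `auc_test`,
#'   `threshold_maxsss`, `beta_history` and flags filled in.
#' @export
tune_beta <- function(presences, background, stack, split = 0.3,
                      overfit_gap = 0.05, max_doublings = 5L, seed = 1,
                      species = "species",
                      transforms = c("linear", "quadratic")) {
  stopifnot(split > 0, split < 1)
  n <- nrow(presences)
  if (n < 10L)
    return(fit_maxent(presences, background, stack, species = species))
  no_split <- n < 20L
  if (no_split) {
    warning(sprintf("species '%s': too few presences to split; no-split fit", species))
    idx_test <- integer(0)
  } else {
    idx_test <- with_seed(seed, sample.int(n, size = max(1L, round(split * n))))
  }
  tr <- if (length(idx_test)) presences[-idx_test, , drop = FALSE] else presences
  te <- presences[idx_test, , drop = FALSE]
  cov_b <- extract_stack_at(stack, background$x, background$y)
  cov_b <- cov_b[stats::complete.cases(cov_b), , drop = FALSE]
  beta <- 1
  history <- data.frame(beta = numeric(0), auc_train = numeric(0),
                        auc_test = numeric(0), gap = numeric(0))
  model <- NULL
  for (step in seq_len(max_doublings + 1L)) {
    model <- fit_maxent(tr, background, stack, beta = beta,
                        species = species, transforms = transforms)
    cov_tr <- extract_stack_at(stack, tr$x, tr$y)
    cov_tr <- cov_tr[stats::complete.cases(cov_tr), , drop = FALSE]
    s_tr <- score_points(model, cov_tr)
    s_b <- score_points(model, cov_b)
    model$background_raw <- s_b
    model$auc_train <- evaluate_auc(s_tr, s_b)
    if (nrow(te)) {
      cov_te <- extract_stack_at(stack, te$x, te$y)
      cov_te <- cov_te[stats::complete.cases(cov_te), , drop = FALSE]
      s_te <- score_points(model, cov_te)
      model$auc_test <- evaluate_auc(s_te, s_b)
      model$threshold_maxsss <- threshold_maxsss(c(s_tr, s_te), s_b)
    } else {
      model$auc_test <- NA_real_
      model$threshold_maxsss <- threshold_maxsss(s_tr, s_b)
    }
    gap <- model$auc_train - model$auc_test
    history <- rbind(history, data.frame(beta = beta,
                                         auc_train = model$auc_train,
                                         auc_test = model$auc_test, gap = gap))
    model$beta_history <- history
    model$no_split <- no_split
    if (no_split || !is.finite(gap) || gap <= overfit_gap) {
      model$overfit_flag <- FALSE
      return(model)
    }
    beta <- beta * 2
  }
  warning(sprintf("species '%s': still overfit after %d beta doublings",
                  species, max_doublings))
  model$overfit_flag <- TRUE
  model
}

#' Binarize a suitability map at a threshold
#'
#' @param suitability `raster_grid` of scores.
#' @param threshold cells with score >= threshold become 1, else 0; nodata
#'   propagates.
#' @return binary `raster_grid`.
#' @export
binarize_suitability <- function(suitability, threshold) {
  v <- suitability$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  raster_grid(out, suitability$origin_x, suitability$origin_y,
              suitability$cell_size, suitability$nodata, suitability$crs_tag)
}

#' Ensemble binary species maps into a prey-richness layer
#'
#' Cellwise integer sum of per-species binary grids; nodata in any input
#' makes the cell nodata. Inputs must be strictly binary.
#'
#' @param binary_grids list of co-registered binary (0/1/nodata) grids.
#' @return `raster_grid` of richness, 0..n_species.
#' @export
build_richness <- function(binary_grids) {
  stopifnot(length(binary_grids) >= 1L)
  check_coregistered(binary_grids)
  for (i in seq_along(binary_grids)) {
    v <- binary_grids[[i]]$values
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop(sprintf("input grid %d is not binary", i))
  }
  acc <- binary_grids[[1L]]$values
  for (i in seq_along(binary_grids)[-1L]) acc <- acc + binary_grids[[i]]$values
  g <- binary_grids[[1L]]
  raster_grid(acc, g$origin_x, g$origin_y, g$cell_size, g$nodata, g$crs_tag)
}
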