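#' Canonical candidate covariate codes
#'
#' The eight candidate habitat covariates: bathymetry, chlorophyll-a, sea
#' surface temperature and sea surface height, plus their 3x3
#' proportional-change gradients. `normalize_terms()` maps case variants
#' (e.g. `"CHLA.G3"`) onto the canonical codes.
#'
#' @return Character vector of the eight canonical codes.
#' @export
canonical_terms <- function() {
  c("BAT", "BAT.G3", "CHLa", "CHLa.G3", "SST", "SST.G3", "SSH", "SSH.G3")
}

#' @rdname canonical_terms
#' @param terms Character vector of term names (aliases accepted
#'   case-insensitively).
#' @export
normalize_terms <- function(terms) {
  canon <- canonical_terms()
  idx <- match(toupper(terms), toupper(canon))
  if (any(is.na(idx)))
    stop("unknown term(s): ", paste(terms[is.na(idx)], collapse = ", "))
  canon[idx]
}

model_key <- function(terms) {
  if (length(terms) == 0) "1" else paste(sort(terms), collapse = " + ")
}

key_terms <- function(key) {
  if (key == "1") character(0) else strsplit(key, " + ", fixed = TRUE)[[1]]
}

#' Fit a binomial (logit) presence/absence GLM
#'
#' Maximum-likelihood logistic regression of cell occupancy on standardized
#' covariates, via [stats::glm()]. Complete or quasi-complete separation
#' (fitted probabilities numerically 0 or 1) is detected and flagged; such
#' fits are reported as unconverged rather than used silently.
#'
#' @param data Data frame with a 0/1 response column `occ` and one column
#'   per covariate; no missing values.
#' @param terms Character vector of covariate names (possibly empty for the
#'   intercept-only model).
#' @return Object of class `habitat_fit`: `terms`, `coefficients`,
#'   `log_likelihood`, `aic` (`-2 logLik + 2 k`), `n_obs`, `converged`,
#'   `separation`.
#' @export
fit_glm_binomial <- function(data, terms = character(0)) {
  if (!"occ" %in% names(data)) stop("data must contain a 0/1 column 'occ'")
  if (length(unique(data$occ)) < 2)
    stop("response has a single class; both presences and absences are required")
  if (anyNA(data[c("occ", terms)])) stop("missing values in response or covariates")
  rhs <- if (length(terms) == 0) "1" else
    paste(sprintf("`%s`", terms), collapse = " + ")
  f <- stats::as.formula(paste("occ ~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  names(co) <- gsub("`", "", names(co))
  structure(list(terms = terms, coefficients = co,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), n_obs = nrow(data),
                 converged = fit$converged, separation = separation),
            class = "habitat_fit")
}

#' @export
print.habitat_fit <- function(x, ...) {
  cat(sprintf("habitat_fit: occ ~ %s | AIC %.2f, n %d%s\n",
              model_key(x$terms), x$aic, x$n_obs,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Predict occupancy probabilities from a fitted model
#' @param fit A `habitat_fit`.
#' @param newdata Data frame containing every model term.
#' @return Numeric vector of probabilities.
#' @export
predict_fit <- function(fit, newdata) {
  eta <- rep(fit$coefficients[["(Intercept)"]], nrow(newdata))
  for (v in fit$terms) eta <- eta + fit$coefficients[[v]] * newdata[[v]]
  stats::plogis(eta)
}

#' Backward-forward stepwise AIC selection
#'
#' Starts from the full model and repeatedly applies the single-term
#' deletion or addition that most decreases AIC, stopping when no move
#' decreases it. Ties are broken toward the smaller model, then
#' lexicographically. Every candidate model evaluated along the way is
#' recorded with its AIC, so competing models can be tabulated afterwards.
#'
#' @param data Model data frame (see [fit_glm_binomial()]).
#' @param candidates Full candidate term set (scope for additions).
#' @param start Starting model terms (default: the full candidate set).
#' @return Object of class `stepwise_fit`: `best_terms`, `best_fit`, and
#'   `path` (data frame of every evaluated model: `model`, `n_terms`,
#'   `aic`).
#' @export
stepwise_aic <- function(data, candidates, start = candidates) {
  candidates <- unique(candidates)
  cache <- new.env(parent = emptyenv())
  fit_cached <- function(terms) {
    k <- model_key(terms)
    if (exists(k, envir = cache, inherits = FALSE)) return(cache[[k]])
    f <- tryCatch(fit_glm_binomial(data, terms),
                  error = function(e) structure(
                    list(terms = terms, aic = Inf, converged = FALSE,
                         separation = FALSE),
                    class = "habitat_fit"))
    cache[[k]] <- f
    f
  }
  current <- sort(start)
  cur_fit <- fit_cached(current)
  path <- list(data.frame(model = model_key(current),
                          n_terms = length(current), aic = cur_fit$aic))
  repeat {
    moves <- c(lapply(current, function(t) setdiff(current, t)),
               lapply(setdiff(candidates, current),
                      function(t) sort(c(current, t))))
    if (length(moves) == 0) break
    keys <- vapply(moves, model_key, character(1))
    aics <- vapply(moves, function(m) fit_cached(m)$aic, numeric(1))
    nts <- lengths(moves)
    path[[length(path) + 1L]] <- data.frame(model = keys, n_terms = nts,
                                            aic = aics)
    best <- order(aics, nts, keys)[1]
    if (aics[best] < cur_fit$aic - 1e-9) {
      current <- moves[[best]]
      cur_fit <- fit_cached(current)
    } else break
  }
  path <- do.call(rbind, path)
  path <- path[!duplicated(path$model), ]
  rownames(path) <- NULL
  structure(list(best_terms = current, best_fit = cur_fit, path = path),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise_fit: best occ ~ %s (AIC %.2f); %d models evaluated\n",
              model_key(x$best_terms), x$best_fit$aic, nrow(x$path)))
  invisible(x)
}

#' Akaike weights
#'
#' Relative model likelihoods `w_i = exp(-D_i/2) / sum_j exp(-D_j/2)` with
#' `D_i = AIC_i - min(AIC)`. Weights sum to 1 and are invariant to adding a
#' constant to every AIC.
#'
#' @param aics Numeric vector of AIC values (at least one finite).
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) == 0) stop("empty AIC vector")
  if (!any(is.finite(aics))) stop("no finite AIC values")
  d <- aics - min(aics, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Competing-model table
#'
#' Refits every unique model evaluated during a stepwise search on the same
#' data, keeps those within `delta_max` AIC units of the best, and reports
#' them best-first with their AIC difference and Akaike weight (normalized
#' over the retained set). Ties sort by term count, then lexicographically.
#' The `formula_signed` column prefixes each term with the sign of its
#' fitted coefficient.
#'
#' @param step A `stepwise_fit`.
#' @param data The data frame the search was run on.
#' @param delta_max AIC-difference cutoff for competing models (default 2).
#' @return Data frame: `model`, `formula_signed`, `n_terms`, `aic`,
#'   `delta_aic`, `akaike_weight`.
#' @export
competing_models <- function(step, data, delta_max = 2) {
  stopifnot(inherits(step, "stepwise_fit"))
  keys <- unique(step$path$model)
  fits <- lapply(keys, function(k) fit_glm_binomial(data, key_terms(k)))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  nts <- vapply(fits, function(f) length(f$terms), integer(1))
  delta <- aic - min(aic)
  keep <- which(delta <= delta_max)
  ord <- keep[order(aic[keep], nts[keep], keys[keep])]
  signed <- vapply(fits[ord], function(f) {
    if (length(f$terms) == 0) return("1")
    co <- f$coefficients[f$terms]
    paste0(ifelse(co > 0, "+", "-"), f$terms, collapse = " ")
  }, character(1))
  data.frame(model = keys[ord], formula_signed = signed,
             n_terms = nts[ord], aic = aic[ord],
             delta_aic = aic[ord] - min(aic),
             akaike_weight = akaike_weights(aic[ord]))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney estimate of the area under the ROC curve: the probability
#' that a randomly chosen positive scores higher than a randomly chosen
#' negative, with ties counting 1/2. Invariant under strictly increasing
#' transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) class labels; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the replicate GLM ensemble
#'
#' For each replicate `r`, combines the (fixed) presence cells with
#' pseudo-absence set `r` into a balanced sample, draws a stratified 70/30
#' train/test partition of each class, runs backward-forward stepwise AIC
#' selection on the training portion, and scores the selected model's
#' test-set AUC. Replicates whose selected fit fails to converge or shows
#' separation are excluded from summaries and counted. The ensemble summary
#' reports the mean AUC with its standard error over successful replicates,
#' how often each term was selected (and with which sign), and whether the
#' ensemble is usable (mean AUC >= 0.7).
#'
#' @param presences A `presence_set` (or integer cell ids).
#' @param design A `pa_design` with at least `n_rep` sets.
#' @param stack A standardized `env_stack`.
#' @param candidates Candidate terms (default [canonical_terms()]
#'   intersected with the stack's layers).
#' @param n_rep Number of replicates (default 100).
#' @param train_frac Training fraction per class (default 0.7).
#' @param seed Integer seed; results are bit-identical under a repeated
#'   seed.
#' @param shuffle_labels If `TRUE`, the presence/absence labels of each
#'   replicate's data are randomly permuted before splitting — a null
#'   randomization under which AUC should centre on 0.5.
#' @return Object of class `replicate_ensemble`: per-replicate results,
#'   `auc` vector, `mean_auc`, `se_auc`, `term_summary`, `usable`,
#'   `n_converged`, `n_failed`.
#' @export
run_replicates <- function(presences, design, stack,
                           candidates = intersect(canonical_terms(),
                                                  names(stack$layers)),
                           n_rep = 100, train_frac = 0.7, seed,
                           shuffle_labels = FALSE) {
  stopifnot(inherits(design, "pa_design"))
  if (length(design$sets) < n_rep)
    stop(sprintf("design has %d pseudo-absence sets but %d replicates requested",
                 length(design$sets), n_rep))
  pres_cells <- if (inherits(presences, "presence_set")) presences$cells else
    as.integer(presences)
  x_pres <- stack_values_at(stack, pres_cells, candidates)
  set.seed(seed)
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    abs_cells <- design$sets[[r]]
    df <- rbind(cbind(occ = 1, x_pres),
                cbind(occ = 0, stack_values_at(stack, abs_cells, candidates)))
    cells <- c(pres_cells, abs_cells)
    if (shuffle_labels) df$occ <- sample(df$occ)
    i1 <- which(df$occ == 1); i0 <- which(df$occ == 0)
    tr <- c(sample(i1, round(train_frac * length(i1))),
            sample(i0, round(train_frac * length(i0))))
    te <- setdiff(seq_len(nrow(df)), tr)
    sw <- stepwise_aic(df[tr, , drop = FALSE], candidates)
    fit <- sw$best_fit
    ok <- isTRUE(fit$converged) && !isTRUE(fit$separation)
    a <- if (ok) auc(predict_fit(fit, df[te, , drop = FALSE]),
                     df$occ[te] == 1) else NA_real_
    reps[[r]] <- list(replicate = r, pseudo_absence_set = r,
                      train_cells = cells[tr], test_cells = cells[te],
                      terms = fit$terms, coefficients = fit$coefficients,
                      aic = fit$aic, auc = a, converged = ok)
  }
  ok <- vapply(reps, function(x) x$converged, logical(1))
  aucs <- vapply(reps, function(x) x$auc, numeric(1))
  n_ok <- sum(ok)
  mean_auc <- mean(aucs[ok])
  se_auc <- if (n_ok >= 2) stats::sd(aucs[ok]) / sqrt(n_ok) else NA_real_
  term_summary <- do.call(rbind, lapply(candidates, function(v) {
    sel <- vapply(reps, function(x) x$converged && v %in% x$terms, logical(1))
    co <- vapply(reps[sel], function(x) x$coefficients[[v]], numeric(1))
    data.frame(term = v, n_selected = sum(sel),
               freq_selected = sum(sel) / n_ok,
               n_positive = sum(co > 0), n_negative = sum(co < 0),
               mean_coefficient = if (any(sel)) mean(co) else NA_real_)
  }))
  structure(list(replicates = reps, auc = aucs, mean_auc = mean_auc,
                 se_auc = se_auc, term_summary = term_summary,
                 usable = isTRUE(mean_auc >= 0.7),
                 n_rep = n_rep, n_converged = n_ok, n_failed = n_rep - n_ok,
                 candidates = candidates, seed = seed),
            class = "replicate_ensemble")
}

#' @export
print.replicate_ensemble <- function(x, ...) {
  cat(sprintf("replicate_ensemble: %d/%d replicates converged; mean AUC %.3f +/- %.3f (SE)%s\n",
              x$n_converged, x$n_rep, x$mean_auc, x$se_auc,
              if (x$usable) " [usable]" else " [not usable]"))
  sel <- x$term_summary[order(-x$term_summary$n_selected), ]
  cat("  selection frequencies:",
      paste(sprintf("%s %d", sel$term, sel$n_selected), collapse = ", "), "\n")
  invisible(x)
}

#' Write the replicate table to CSV
#'
#' One row per replicate: selected terms, coefficient values (empty for
#' unselected terms), AIC and test AUC.
#'
#' @param ensemble A `replicate_ensemble`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_replicates_csv <- function(ensemble, file) {
  rows <- lapply(ensemble$replicates, function(x) {
    row <- data.frame(replicate = x$replicate,
                      terms = model_key(x$terms),
                      aic = x$aic, auc = x$auc, converged = x$converged)
    for (v in ensemble$candidates)
      row[[paste0("coef_", v)]] <-
        if (v %in% x$terms) x$coefficients[[v]] else NA_real_
    row
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
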