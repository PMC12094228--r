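# Locked ensemble scoring: six penalized logistic regressions (PLRs) over
# repeat-family and epigenetic feature blocks are stacked into an ARTEMIS
# score; a PLR on the principal components of the bin-level fragmentation
# ratios and a PLR on the arm z-scores are then stacked with the ARTEMIS
# score into the final model, whose output is a tumor probability in [0,1].
#
# Component PLRs are ridge (L2) logistic regressions with the penalty
# strength selected by cross-validated deviance; stacking uses out-of-fold
# component scores so the stacker never sees resubstitution fits.

#' Identify feature blocks by column-name prefix
#'
#' Feature matrices use a naming convention: `rep_<FAMILY>_*` for repeat
#' family blocks, `epi_*` for epigenetic coverage, `ratio_*` for bin-level
#' fragmentation ratios, `armz_*` for arm z-scores.
#'
#' @param feature_names Character vector of column names.
#' @return Named list of character vectors, one per block (five repeat
#'   families + epi + ratio + armz).
#' @export
feature_blocks <- function(feature_names) {
  rep_cols <- feature_names[str_starts(feature_names, "rep_")]
  fams <- unique(sub("^rep_([^_]+)_.*$", "\\1", rep_cols))
  blocks <- lapply(fams, function(f) {
    rep_cols[str_starts(rep_cols, paste0("rep_", f, "_"))]
  })
  names(blocks) <- paste0("rep_", fams)
  blocks$epi <- feature_names[str_starts(feature_names, "epi_")]
  blocks$ratio <- feature_names[str_starts(feature_names, "ratio_")]
  blocks$armz <- feature_names[str_starts(feature_names, "armz_")]
  blocks[vapply(blocks, length, 1L) > 0]
}

as_label01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) > 2) abort("more than two label classes")
    # "cancer" (or alphabetically first of other labelings) is the positive class
    pos <- if ("cancer" %in% lv) "cancer" else lv[length(lv)]
    return(as.integer(labels == pos))
  }
  as.integer(labels)
}

#' Fit one component penalized logistic regression
#'
#' Ridge logistic regression on one feature block with penalty strength
#' chosen by k-fold cross-validated deviance; out-of-fold scores (each
#' sample scored by the model fit with its fold held out, at the selected
#' penalty) are returned for downstream stacking.
#'
#' @param x Numeric matrix or tibble (samples x features).
#' @param labels Binary labels (0/1, logical, or "cancer"/"non-cancer").
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param alpha Elastic-net mixing (0 = ridge, default).
#' @return A `component_plr` object: coefficients, intercept, lambda,
#'   feature names, out-of-fold scores (`oof`), fitted scores.
#' @export
fit_component_plr <- function(x, labels, folds = 5, seed = 1, alpha = 0) {
  x <- as.matrix(x)
  y <- as_label01(labels)
  if (length(unique(y)) < 2) {
    abort("labels contain a single class", class = "cfmonitor_single_class")
  }
  n <- nrow(x)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          foldid = foldid, type.measure = "deviance",
                          standardize = TRUE)
  lambda <- cv$lambda.min
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                         lambda = lambda, standardize = TRUE)
  oof <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    hold <- foldid == k
    fit_k <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                            family = "binomial", alpha = alpha,
                            lambda = lambda, standardize = TRUE)
    oof[hold] <- as.numeric(
      predict(fit_k, x[hold, , drop = FALSE], type = "response"))
  }
  beta <- as.numeric(coef(full))
  structure(list(
    intercept = beta[1],
    coefficients = setNames(beta[-1], colnames(x)),
    lambda = lambda,
    features = colnames(x),
    seed = seed,
    alpha = alpha,
    oof = oof,
    fitted = as.numeric(predict(full, x, type = "response"))
  ), class = "component_plr")
}

score_plr <- function(plr, x) {
  x <- as.matrix(x)[, plr$features, drop = FALSE]
  as.numeric(inv_logit(plr$intercept + x %*% plr$coefficients))
}

#' Fit the fragmentation principal-component PLR
#'
#' Mean-imputes missing bin ratios (training-cohort means), extracts the
#' smallest number of principal components whose cumulative explained
#' variance reaches `var_explained`, and fits a ridge logistic regression
#' on the component scores.
#'
#' @param x Ratio matrix/tibble (samples x bins; NAs allowed).
#' @param labels Binary labels.
#' @param var_explained Cumulative variance target (default 0.95; 1 keeps
#'   all components).
#' @param folds,seed,alpha As in [fit_component_plr()].
#' @return A `pc_plr` object: imputation means, PCA center and rotation,
#'   number of components, and the embedded `component_plr`.
#' @export
fit_fragmentation_pc_plr <- function(x, labels, var_explained = 0.95,
                                     folds = 5, seed = 1, alpha = 0) {
  x <- as.matrix(x)
  impute_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- impute_means[j]
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_comp <- if (var_explained >= 1) length(cum) else
    which(cum >= var_explained)[1]
  scores <- pc$x[, seq_len(n_comp), drop = FALSE]
  plr <- fit_component_plr(scores, labels, folds = folds, seed = seed,
                           alpha = alpha)
  structure(list(
    impute_means = impute_means,
    center = pc$center,
    rotation = pc$rotation[, seq_len(n_comp), drop = FALSE],
    n_components = n_comp,
    var_explained = var_explained,
    features = colnames(x),
    plr = plr,
    oof = plr$oof,
    fitted = plr$fitted
  ), class = "pc_plr")
}

score_pc_plr <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- model$impute_means[j]
  }
  scores <- sweep(x, 2, model$center) %*% model$rotation
  colnames(scores) <- model$plr$features
  score_plr(model$plr, scores)
}

#' Fit a PLR on chromosome-arm z-scores
#'
#' Identical machinery to [fit_component_plr()], applied to the arm
#' z-score block.
#'
#' @inheritParams fit_component_plr
#' @return A `component_plr`.
#' @export
fit_armz_plr <- function(x, labels, folds = 5, seed = 1, alpha = 0) {
  fit_component_plr(x, labels, folds = folds, seed = seed, alpha = alpha)
}

# Logistic stacker with a small fixed L2 penalty: component scores often
# separate the training cohort perfectly, where unpenalized logistic
# regression diverges and saturates; weak ridge keeps the stacker finite
# and the output usable as a probability.
logistic_stacker <- function(score_matrix, y, lambda = 0.01) {
  m <- as.matrix(score_matrix)
  padded <- ncol(m) < 2  # glmnet needs >= 2 columns
  x <- if (padded) cbind(m, .pad = 0) else m
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(coef(fit))
  coefs <- setNames(beta[-1], colnames(x))
  if (padded) coefs <- coefs[colnames(m)]
  list(intercept = beta[1],
       coefficients = coefs,
       inputs = colnames(m),
       fitted = as.numeric(predict(fit, x, type = "response")))
}

score_stacker <- function(st, score_matrix) {
  m <- as.matrix(score_matrix[, st$inputs, drop = FALSE])
  as.numeric(inv_logit(st$intercept + m %*% st$coefficients))
}

#' Stack component scores into the ARTEMIS score
#'
#' Logistic stacker over the out-of-fold scores of the six repeat/
#' epigenetic component PLRs.
#'
#' @param oof_scores Matrix/tibble of out-of-fold component scores
#'   (samples x components, named columns).
#' @param labels Binary labels.
#' @return A `stacker` list (intercept, coefficients, inputs, fitted).
#' @export
fit_artemis_ensemble <- function(oof_scores, labels) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2) {
    abort("labels contain a single class", class = "cfmonitor_single_class")
  }
  st <- logistic_stacker(as.matrix(oof_scores), y)
  structure(st, class = "stacker")
}

#' Stack the ARTEMIS, fragmentation-PC and arm-z scores
#'
#' Final logistic stacker over the three intermediate scores; together
#' with the fitted components this constitutes the model that is then
#' locked.
#'
#' @param scores Matrix/tibble with columns `artemis`, `ratio_pc`, `armz`.
#' @param labels Binary labels.
#' @return A `stacker` list.
#' @export
fit_final_stack <- function(scores, labels) {
  fit_artemis_ensemble(scores, labels)
}

#' Train the full locked ensemble model
#'
#' End-to-end training on a labeled reference cohort: fits one PLR per
#' repeat family and one on the epigenetic block, stacks their out-of-fold
#' scores into the ARTEMIS score, fits the fragmentation-PC PLR and the
#' arm-z PLR, stacks the three scores into the final model, and locks the
#' result (feature panel recorded with a checksum; application never
#' refits).
#'
#' @param features Tibble/matrix of training features (block naming per
#'   [feature_blocks()]).
#' @param labels Binary labels ("cancer"/"non-cancer", logical or 0/1).
#' @param seed Integer seed (fold assignment in every component).
#' @param folds CV folds per component.
#' @param var_explained Variance target of the fragmentation PCA.
#' @return A `locked_ensemble_model`.
#' @examples
#' cfg <- sim_config(seed = 2, n_training_per_class = 25,
#'                   fragments_per_sample = 2000, n_reference_healthy = 3)
#' panel <- simulate_reference_panel(cfg)
#' feats <- panel$training[, -(1:3)]
#' model <- train_artemis_delfi(feats, panel$training$label, seed = 2)
#' @export
train_artemis_delfi <- function(features, labels, seed = 1, folds = 5,
                                var_explained = 0.95) {
  features <- tibble::as_tibble(features)
  blocks <- feature_blocks(names(features))
  comp_names <- setdiff(names(blocks), c("ratio", "armz"))
  if (!length(comp_names)) abort("no repeat/epigenetic feature blocks found")
  y <- as_label01(labels)

  components <- lapply(seq_along(comp_names), function(i) {
    nm <- comp_names[i]
    fit_component_plr(features[, blocks[[nm]], drop = FALSE], y,
                      folds = folds, seed = derive_seed(seed, i))
  })
  names(components) <- comp_names
  oof <- vapply(components, function(m) m$oof, numeric(nrow(features)))
  artemis <- fit_artemis_ensemble(oof, y)
  artemis_oof <- score_stacker(artemis, oof)

  ratio_model <- fit_fragmentation_pc_plr(
    features[, blocks$ratio, drop = FALSE], y,
    var_explained = var_explained, folds = folds,
    seed = derive_seed(seed, 101L))
  armz_model <- fit_armz_plr(features[, blocks$armz, drop = FALSE], y,
                             folds = folds, seed = derive_seed(seed, 102L))

  top <- cbind(artemis = artemis_oof, ratio_pc = ratio_model$oof,
               armz = armz_model$oof)
  final <- fit_final_stack(top, y)

  panel <- sort(unlist(blocks, use.names = FALSE))
  model <- structure(list(
    components = components,
    artemis_stacker = artemis,
    ratio_model = ratio_model,
    armz_model = armz_model,
    final_stacker = final,
    blocks = blocks,
    panel = panel,
    seed = seed,
    folds = folds,
    checksum = NA_character_,
    training_scores = NULL
  ), class = "locked_ensemble_model")
  model$checksum <- model_checksum(model)
  model$training_scores <- apply_locked_model(model, features)$score
  model
}

model_checksum <- function(model) {
  payload <- paste(
    paste(model$panel, collapse = ","),
    paste(sprintf("%.12g", unlist(lapply(model$components, function(m) {
      c(m$intercept, m$coefficients)
    }))), collapse = ","),
    paste(sprintf("%.12g", c(model$final_stacker$intercept,
                             model$final_stacker$coefficients)),
          collapse = ","),
    sep = "|")
  fnv1a32(payload)
}

#' Apply a locked ensemble model to new samples
#'
#' Pure application: verifies the feature panel (hard error naming missing
#' features; checksum guards against post-training mutation), computes each
#' component score, the ARTEMIS stack, the fragmentation-PC and arm-z
#' scores, and the final score in [0, 1]. No state is mutated and nothing
#' is refit.
#'
#' @param model A `locked_ensemble_model`.
#' @param features Tibble/matrix of sample features with the training
#'   column names.
#' @return Tibble: one row per sample with `artemis`, `ratio_pc`, `armz`,
#'   and the final `score`.
#' @export
apply_locked_model <- function(model, features) {
  stopifnot(inherits(model, "locked_ensemble_model"))
  if (!is.na(model$checksum) && model_checksum(model) != model$checksum) {
    abort("locked model failed its checksum; it has been altered since training")
  }
  features <- tibble::as_tibble(features)
  missing <- setdiff(model$panel, names(features))
  if (length(missing)) {
    abort(paste0("feature panel mismatch; missing: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10)))
  }
  comp_scores <- vapply(model$components, function(m) {
    score_plr(m, features)
  }, numeric(nrow(features)))
  if (nrow(features) == 1L) comp_scores <- matrix(
    comp_scores, nrow = 1, dimnames = list(NULL, names(model$components)))
  artemis <- score_stacker(model$artemis_stacker, comp_scores)
  ratio_pc <- score_pc_plr(model$ratio_model, features)
  armz <- score_plr(model$armz_model, features)
  top <- cbind(artemis = artemis, ratio_pc = ratio_pc, armz = armz)
  tibble::tibble(
    artemis = artemis, ratio_pc = ratio_pc, armz = armz,
    score = score_stacker(model$final_stacker, top))
}

#' @export
print.locked_ensemble_model <- function(x, ...) {
  cat("<locked_ensemble_model>\n")
  cat(sprintf("  %d component PLRs + fragmentation-PC (%d comps) + arm-z PLR\n",
              length(x$components), x$ratio_model$n_components))
  cat(sprintf("  panel: %d features, checksum %s, seed %d\n",
              length(x$panel), x$checksum, x$seed))
  invisible(x)
}

#' @export
tidy.locked_ensemble_model <- function(x, ...) {
  comp <- purrr::imap(x$components, function(m, nm) {
    tibble::tibble(component = nm, term = c("(Intercept)", m$features),
                   estimate = c(m$intercept, unname(m$coefficients)))
  }) |> purrr::list_rbind()
  stack <- tibble::tibble(
    component = "final_stacker",
    term = c("(Intercept)", x$final_stacker$inputs),
    estimate = c(x$final_stacker$intercept,
                 unname(x$final_stacker$coefficients)))
  dplyr::bind_rows(comp, stack)
}

#' @export
glance.locked_ensemble_model <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$components),
    n_pca_components = x$ratio_model$n_components,
    n_features = length(x$panel),
    seed = x$seed,
    checksum = x$checksum)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#'
#' @param labels Binary labels (positive class per [fit_component_plr()]
#'   conventions).
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  y <- as_label01(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("need both classes for AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize a locked ensemble model to JSON
#'
#' Versioned JSON holding every coefficient, the PCA rotation, the feature
#' panel and the training seed; [read_ensemble_model()] reconstructs an
#' identical model (checksum verified).
#'
#' @param model A `locked_ensemble_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_model <- function(model, path) {
  stopifnot(inherits(model, "locked_ensemble_model"))
  ser_plr <- function(m) {
    list(intercept = m$intercept, coefficients = as.list(m$coefficients),
         lambda = m$lambda, features = m$features, seed = m$seed,
         alpha = m$alpha)
  }
  ser_st <- function(s) {
    list(intercept = s$intercept, coefficients = as.list(s$coefficients),
         inputs = s$inputs)
  }
  obj <- list(
    format = "cfmonitor_ensemble",
    version = 1L,
    seed = model$seed,
    folds = model$folds,
    checksum = model$checksum,
    panel = model$panel,
    blocks = model$blocks,
    components = lapply(model$components, ser_plr),
    artemis_stacker = ser_st(model$artemis_stacker),
    armz_model = ser_plr(model$armz_model),
    ratio_model = list(
      impute_means = as.list(model$ratio_model$impute_means),
      center = as.list(model$ratio_model$center),
      rotation = as.numeric(model$ratio_model$rotation),
      rotation_dim = dim(model$ratio_model$rotation),
      rotation_rows = rownames(model$ratio_model$rotation),
      n_components = model$ratio_model$n_components,
      var_explained = model$ratio_model$var_explained,
      features = model$ratio_model$features,
      plr = ser_plr(model$ratio_model$plr)),
    final_stacker = ser_st(model$final_stacker),
    training_scores = model$training_scores)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ensemble_model
#' @export
read_ensemble_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cfmonitor_ensemble")) {
    abort("not a cfmonitor ensemble model file")
  }
  de_plr <- function(m) {
    structure(list(
      intercept = m$intercept,
      coefficients = unlist(m$coefficients),
      lambda = m$lambda, features = m$features, seed = m$seed,
      alpha = m$alpha, oof = NULL, fitted = NULL), class = "component_plr")
  }
  de_st <- function(s) {
    structure(list(intercept = s$intercept,
                   coefficients = unlist(s$coefficients),
                   inputs = s$inputs), class = "stacker")
  }
  rot <- matrix(obj$ratio_model$rotation,
                nrow = obj$ratio_model$rotation_dim[1],
                ncol = obj$ratio_model$rotation_dim[2])
  rownames(rot) <- obj$ratio_model$rotation_rows
  ratio_model <- structure(list(
    impute_means = unlist(obj$ratio_model$impute_means),
    center = unlist(obj$ratio_model$center),
    rotation = rot,
    n_components = obj$ratio_model$n_components,
    var_explained = obj$ratio_model$var_explained,
    features = obj$ratio_model$features,
    plr = de_plr(obj$ratio_model$plr)), class = "pc_plr")
  model <- structure(list(
    components = lapply(obj$components, de_plr),
    artemis_stacker = de_st(obj$artemis_stacker),
    ratio_model = ratio_model,
    armz_model = de_plr(obj$armz_model),
    final_stacker = de_st(obj$final_stacker),
    blocks = obj$blocks,
    panel = obj$panel,
    seed = obj$seed,
    folds = obj$folds,
    checksum = obj$checksum,
    training_scores = obj$training_scores), class = "locked_ensemble_model")
  if (model_checksum(model) != model$checksum) {
    abort("checksum mismatch reading locked model")
  }
  model
}
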