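# Expected direction of each feature: +1 means the +2 charge class has the
# larger mean, -1 means the +3 class does.
.feature_directions <- c(delta_cp = 1, delta_rcp = 1, i_dc = -1, n_bs = -1)

#' Map mixture components to charge states
#'
#' An unsupervised fit leaves the two components unlabeled; this maps them
#' to +2 and +3 using the expected per-class direction of each feature:
#' the complementary-pair features (`delta_cp`, `delta_rcp`) are larger for
#' +2 precursors, while the doubly charged regional intensity (`i_dc`) and
#' the basic-site pseudo-count (`n_bs`) are larger for +3. Each feature in
#' the fit casts one vote comparing the component means; the component
#' winning the majority is labeled +2. A tied vote is resolved by
#' `delta_rcp` (the most discriminant feature) when present, else by the
#' first feature.
#'
#' @param fit A 2-component `gmm_fit` (see [gmm_fit()]).
#' @param feature_names Feature names in the column order of the fitted
#'   matrix; drawn from `c("delta_cp", "delta_rcp", "i_dc", "n_bs")`.
#' @return A list of class `charge_label_map`: `component_plus2`,
#'   `component_plus3` (indices in 1:2) and `votes` (named +1/-1 per
#'   feature, +1 voting component 1 as the +2 class).
#' @export
assign_charge_labels <- function(fit, feature_names) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (nrow(fit$params$means) != 2) stop("charge labeling requires a 2-component fit")
  stopifnot(length(feature_names) == ncol(fit$params$means),
            all(feature_names %in% names(.feature_directions)))
  diffs <- fit$params$means[1, ] - fit$params$means[2, ]  # >0: comp 1 larger
  votes <- sign(diffs) * .feature_directions[feature_names]
  names(votes) <- feature_names
  tally <- sum(votes)
  if (tally == 0) {
    tie_feat <- if ("delta_rcp" %in% feature_names) "delta_rcp" else feature_names[1]
    tally <- votes[[tie_feat]]
  }
  comp2 <- if (tally >= 0) 1L else 2L
  structure(
    list(component_plus2 = comp2, component_plus3 = 3L - comp2, votes = votes),
    class = "charge_label_map"
  )
}

.predict_from_resp <- function(resp, map, threshold) {
  posterior_plus3 <- resp[, map$component_plus3]
  list(
    posterior_plus3 = posterior_plus3,
    # tie at the threshold resolves to the (more common) +2 state
    predicted_charge = ifelse(posterior_plus3 > threshold, 3L, 2L)
  )
}

#' Fit the unsupervised charge-state classifier
#'
#' The main entry point: computes the four charge-state features for every
#' spectrum, scales the selected subset to unit variance, fits a
#' 2-component spherical Gaussian mixture by EM, maps the components to the
#' +2/+3 charge states from the expected feature directions, and assigns
#' each spectrum the charge whose posterior responsibility wins. No labels
#' are used anywhere in the fit; `CHARGE` annotations in the input, when
#' present, are carried through for evaluation only.
#'
#' @param x An [spectrum_collection()], or a path to an MGF file.
#' @param features Ordered feature subset used for clustering; default the
#'   three most discriminant, `c("delta_cp", "delta_rcp", "i_dc")`.
#' @param constants A [mass_constants()] object.
#' @param tolerance Fragment mass-match window (Da), default 0.5 as typical
#'   for ion-trap CID.
#' @param losses_enabled Consider single neutral-loss variants in the pair
#'   relations.
#' @param nt Theoretical repeat number for the basic-site pseudo-count.
#' @param threshold Posterior probability of +3 above which a spectrum is
#'   called +3 (a tie goes to +2).
#' @param center Centre feature columns before scaling.
#' @param n_restarts,max_iter,tol_ll,var_floor,seed Passed to [gmm_fit()].
#' @return An object of class `charge_gmm` with elements `features_raw`
#'   (N x 4 matrix of all four features), `matrix` (the fitted
#'   `feature_matrix`), `fit` (`gmm_fit`), `label_map`, `threshold`,
#'   `predictions` (data frame ready for [write_predictions()]),
#'   `true_charge`, and `call`.
#' @examples
#' sim <- generate_dataset(sim_params(n_spectra = 60, seed = 7))
#' model <- charge_gmm(sim$collection, seed = 7)
#' model
#' head(model$predictions)
#' @export
charge_gmm <- function(x,
                       features = c("delta_cp", "delta_rcp", "i_dc"),
                       constants = mass_constants(),
                       tolerance = 0.5,
                       losses_enabled = TRUE,
                       nt = 1,
                       threshold = 0.5,
                       center = FALSE,
                       n_restarts = 10,
                       max_iter = 500,
                       tol_ll = 1e-8,
                       var_floor = 1e-6,
                       seed = NULL) {
  cl <- match.call()
  if (is.character(x)) x <- read_mgf(x)
  stopifnot(inherits(x, "ms_spectrum_collection"))
  all_feats <- c("delta_cp", "delta_rcp", "i_dc", "n_bs")
  stopifnot(all(features %in% all_feats), length(features) >= 1)

  raw <- t(vapply(
    x$spectra,
    function(sp) spectrum_features(sp, constants, tolerance, losses_enabled, nt),
    numeric(4)
  ))
  rownames(raw) <- spectrum_ids(x)
  fm <- scale_feature_matrix(raw[, features, drop = FALSE], center = center)
  fit <- gmm_fit(fm$scaled, k = 2, n_restarts = n_restarts, max_iter = max_iter,
                 tol_ll = tol_ll, var_floor = var_floor, seed = seed)
  map <- assign_charge_labels(fit, features)
  pred <- .predict_from_resp(fit$responsibilities, map, threshold)

  predictions <- data.frame(
    spectrum_id = spectrum_ids(x),
    delta_cp = raw[, "delta_cp"],
    delta_rcp = raw[, "delta_rcp"],
    i_dc = raw[, "i_dc"],
    n_bs = raw[, "n_bs"],
    posterior_plus3 = pred$posterior_plus3,
    predicted_charge = pred$predicted_charge,
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      call = cl,
      features_raw = raw,
      matrix = fm,
      fit = fit,
      label_map = map,
      threshold = threshold,
      tolerance = tolerance,
      losses_enabled = losses_enabled,
      nt = nt,
      constants = constants,
      predictions = predictions,
      true_charge = true_charges(x)
    ),
    class = "charge_gmm"
  )
}

#' @export
print.charge_gmm <- function(x, ...) {
  n <- nrow(x$predictions)
  n3 <- sum(x$predictions$predicted_charge == 3L)
  cat("Unsupervised charge-state classifier (2-component spherical GMM)\n")
  cat(sprintf("  %d spectra, features: %s\n", n,
              paste(x$matrix$feature_names, collapse = ", ")))
  cat(sprintf("  EM: %d iteration(s), log-likelihood %.3f%s\n",
              x$fit$n_iter, x$fit$log_likelihood,
              if (x$fit$converged) "" else " (not converged)"))
  cat(sprintf("  component %d -> +2, component %d -> +3\n",
              x$label_map$component_plus2, x$label_map$component_plus3))
  cat(sprintf("  predicted: %d spectra +2, %d spectra +3 (threshold %.2f)\n",
              n - n3, n3, x$threshold))
  invisible(x)
}

#' @export
summary.charge_gmm <- function(object, ...) {
  means <- object$fit$params$means
  rownames(means) <- paste0("component_", 1:2)
  colnames(means) <- object$matrix$feature_names
  out <- list(
    model = object,
    component_means = means,
    mixing = object$fit$params$mixing,
    variances = object$fit$params$variances
  )
  tc <- object$true_charge
  if (sum(!is.na(tc)) > 1 && length(unique(tc[!is.na(tc)])) == 2) {
    keep <- !is.na(tc)
    roc <- roc_auc(object$predictions$posterior_plus3[keep], tc[keep])
    out$auc <- roc$auc
    out$accuracy <- mean(object$predictions$predicted_charge[keep] == tc[keep])
    out$class_means <- class_mean_report(object$matrix, tc)
  }
  class(out) <- "summary.charge_gmm"
  out
}

#' @export
print.summary.charge_gmm <- function(x, ...) {
  print(x$model)
  cat("\nComponent means (scaled features):\n")
  print(round(x$component_means, 4))
  cat("mixing:", sprintf("%.3f", x$mixing),
      " variances:", sprintf("%.3f", x$variances), "\n")
  if (!is.null(x$auc)) {
    cat(sprintf("\nAgainst known charges: AUC %.4f, accuracy %.4f\n",
                x$auc, x$accuracy))
    print(x$class_means)
  }
  invisible(x)
}

#' @export
coef.charge_gmm <- function(object, ...) {
  means <- object$fit$params$means
  rownames(means) <- c(
    sprintf("plus%d", c(2, 3))[order(c(object$label_map$component_plus2,
                                       object$label_map$component_plus3))]
  )
  colnames(means) <- object$matrix$feature_names
  means
}

#' @export
logLik.charge_gmm <- function(object, ...) {
  D <- ncol(object$matrix$scaled)
  K <- nrow(object$fit$params$means)
  structure(object$fit$log_likelihood,
            df = K * (D + 1) + (K - 1),
            nobs = nrow(object$matrix$scaled),
            class = "logLik")
}

#' @export
fitted.charge_gmm <- function(object, ...) {
  stats::setNames(object$predictions$posterior_plus3, object$predictions$spectrum_id)
}

#' Predict charge states for spectra
#'
#' With `newdata`, computes the model's features for the new spectra, scales
#' them with the scale factors frozen at fit time, runs one E-step under the
#' fitted mixture and applies the component-to-charge map; without
#' `newdata`, returns the fitted predictions.
#'
#' @param object A [charge_gmm()] model.
#' @param newdata Optional [spectrum_collection()] or MGF path.
#' @param threshold Posterior cut for calling +3; defaults to the model's.
#' @param ... Unused.
#' @return A data frame in the [write_predictions()] column layout.
#' @export
predict.charge_gmm <- function(object, newdata = NULL,
                               threshold = object$threshold, ...) {
  if (is.null(newdata)) {
    pred <- object$predictions
    if (threshold != object$threshold) {
      pred$predicted_charge <- ifelse(pred$posterior_plus3 > threshold, 3L, 2L)
    }
    return(pred)
  }
  if (is.character(newdata)) newdata <- read_mgf(newdata)
  stopifnot(inherits(newdata, "ms_spectrum_collection"))
  raw <- t(vapply(
    newdata$spectra,
    function(sp) spectrum_features(sp, object$constants, object$tolerance,
                                   object$losses_enabled, object$nt),
    numeric(4)
  ))
  sel <- sweep(
    sweep(raw[, object$matrix$feature_names, drop = FALSE],
          2, object$matrix$centers, "-"),
    2, object$matrix$scale_factors, "/"
  )
  resp <- gmm_e_step(sel, object$fit$params)
  pred <- .predict_from_resp(resp, object$label_map, threshold)
  data.frame(
    spectrum_id = spectrum_ids(newdata),
    delta_cp = raw[, "delta_cp"],
    delta_rcp = raw[, "delta_rcp"],
    i_dc = raw[, "i_dc"],
    n_bs = raw[, "n_bs"],
    posterior_plus3 = pred$posterior_plus3,
    predicted_charge = pred$predicted_charge,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Plot a fitted charge-state model
#'
#' Draws the ROC curve against the known charges when they are available;
#' otherwise a scatter of the first two scaled features coloured by
#' predicted charge.
#'
#' @param x A [charge_gmm()] model.
#' @param ... Passed to the underlying plot call.
#' @export
plot.charge_gmm <- function(x, ...) {
  tc <- x$true_charge
  if (sum(!is.na(tc)) > 1 && length(unique(tc[!is.na(tc)])) == 2) {
    keep <- !is.na(tc)
    roc <- roc_auc(x$predictions$posterior_plus3[keep], tc[keep])
    plot(roc, ...)
  } else {
    s <- x$matrix$scaled
    j <- if (ncol(s) >= 2) 2L else 1L
    graphics::plot(s[, 1], s[, j],
                   col = ifelse(x$predictions$predicted_charge == 3L, 2, 4),
                   pch = 20, xlab = x$matrix$feature_names[1],
                   ylab = x$matrix$feature_names[j],
                   main = "Scaled features by predicted charge", ...)
    graphics::legend("topright", legend = c("+2", "+3"), col = c(4, 2), pch = 20)
  }
  invisible(x)
}

#' Simulate feature vectors from a fitted model
#'
#' Draws scaled feature vectors from the fitted two-component spherical
#' mixture (component chosen by the mixing probabilities, then an isotropic
#' Gaussian around its mean).
#'
#' @param object A [charge_gmm()] model.
#' @param nsim Number of feature vectors per replicate.
#' @param seed Optional seed; the RNG state is restored afterwards.
#' @param ... Unused.
#' @return A matrix of `nsim` rows with an attached `component` attribute
#'   giving the drawn component index per row.
#' @export
simulate.charge_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- object$fit$params
  D <- ncol(p$means)
  comp <- sample.int(nrow(p$means), nsim, replace = TRUE, prob = p$mixing)
  out <- p$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(nsim * D, sd = sqrt(p$variances[comp])), nsim, D)
  colnames(out) <- object$matrix$feature_names
  attr(out, "component") <- comp
  out
}
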