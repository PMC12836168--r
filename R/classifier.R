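# Stand-in pixel classifier: a fixed multi-scale feature bank feeding a
# logistic model, trained on labeled synthetic fixtures. Interactive,
# externally-trained tools cannot be reproduced bit-exactly; the pipeline's
# contract is only "a per-pixel foreground probability in [0, 1]", which
# downstream operations treat identically.

# Feature bank: raw intensity, total local energy (local standard deviation
# of the raw image over a fixed window), and per scale: Gaussian smoothing,
# gradient magnitude, Laplacian-of-Gaussian and the local energy of the
# smoothed image over the same window. Energy features at several scales let
# a linear (logistic) model express energy-ratio decisions, which separate
# spatially correlated cell texture from white sensor noise even after
# per-image contrast normalization has destroyed absolute amplitude.
feature_names <- function(scales) {
  c("intensity", "energy_total",
    unlist(lapply(scales, function(s) {
      sprintf(c("gauss_s%g", "gradmag_s%g", "log_s%g", "energy_s%g",
                "energy_ratio_s%g"), s)
    })))
}

local_energy <- function(x, window_sigma = 3) {
  m1 <- blur_matrix(x, window_sigma)
  m2 <- blur_matrix(x^2, window_sigma)
  sqrt(pmax(m2 - m1^2, 0))
}

compute_feature_bank <- function(image, scales) {
  image <- image / max(max(image), 1)  # features on a [0, 1] scale
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  feats <- list(intensity = image, energy_total = local_energy(image))
  for (s in scales) {
    g <- blur_matrix(image, s)
    gx <- (shift_matrix(g, 0, -1, NA) - shift_matrix(g, 0, 1, NA)) / 2
    gy <- (shift_matrix(g, -1, 0, NA) - shift_matrix(g, 1, 0, NA)) / 2
    gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
    feats[[sprintf("gauss_s%g", s)]] <- g
    feats[[sprintf("gradmag_s%g", s)]] <- sqrt(gx^2 + gy^2)
    feats[[sprintf("log_s%g", s)]] <- filter_matrix(g, lap_k)
    e_s <- local_energy(g)
    feats[[sprintf("energy_s%g", s)]] <- e_s
    # energy ratio: fraction of local signal energy below scale s; invariant
    # to the per-image contrast stretch
    feats[[sprintf("energy_ratio_s%g", s)]] <- e_s / (feats$energy_total + 1e-6)
  }
  feats
}

feature_matrix <- function(image, scales, idx = NULL) {
  feats <- compute_feature_bank(image, scales)
  if (is.null(idx)) {
    do.call(cbind, lapply(feats, as.vector))
  } else {
    do.call(cbind, lapply(feats, function(f) f[idx]))
  }
}

#' Train the stand-in pixel classifier
#'
#' Fits a logistic model on a multi-scale feature bank (Gaussian
#' smoothings, gradient magnitude, Laplacian of Gaussian and local standard
#' deviation at each scale, plus raw intensity), using pixels sampled from
#' labeled training images. Ground-truth masks normally come from the
#' synthetic-data generators, which makes the training fully scripted and
#' seeded.
#'
#' @param images List of numeric matrices (training frames).
#' @param masks List of logical matrices (foreground truth, same shapes).
#' @param scales Feature scales in pixels (default `c(1, 2, 4)`).
#' @param n_samples Pixels sampled per class per image (default 2000).
#' @param seed Sampling seed.
#' @param sharpness Multiplier applied to the logistic score at prediction
#'   time (default 6). Values above 1 harden the per-pixel confidence so
#'   probability maps are near-binary, the regime the downstream
#'   thresholding steps are designed for; the 0.5 decision boundary is
#'   unchanged. Set to 1 for raw logistic probabilities.
#' @return An object of class `pixel_classifier` (feature scales, logistic
#'   coefficients, feature standardization constants, sharpness, seed).
#' @export
train_pixel_classifier <- function(images, masks, scales = c(1, 2, 4),
                                   n_samples = 2000, seed = 1, sharpness = 6) {
  stopifnot(length(images) == length(masks))
  xy <- withr::with_seed(seed, {
    parts <- lapply(seq_along(images), function(i) {
      img <- images[[i]]; msk <- masks[[i]]
      stopifnot(identical(dim(img), dim(msk)))
      fg <- which(msk); bg <- which(!msk)
      if (length(fg) == 0L && length(bg) == 0L) return(NULL)
      take <- function(pool) pool[sample.int(length(pool),
                                             min(n_samples, length(pool)))]
      # single-class frames (blank or confluent) contribute that class only
      idx <- c(take(fg), take(bg))
      list(x = feature_matrix(img, scales, idx),
           y = msk[idx])
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    y_all <- unlist(lapply(parts, `[[`, "y"))
    if (length(unique(y_all)) < 2L) {
      stop_chemotax("training set must contain both foreground and background pixels")
    }
    list(x = do.call(rbind, lapply(parts, `[[`, "x")), y = y_all)
  })
  mu <- colMeans(xy$x)
  sg <- apply(xy$x, 2, stats::sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(xy$x, 2, mu), 2, sg, "/")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, xs), xy$y, family = stats::binomial())
  )
  structure(
    list(scales = scales,
         coefficients = stats::setNames(fit$coefficients,
                                        c("(Intercept)", feature_names(scales))),
         feature_mean = stats::setNames(mu, feature_names(scales)),
         feature_sd = stats::setNames(sg, feature_names(scales)),
         sharpness = sharpness, n_train = length(xy$y), seed = seed),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> logistic model on %d features (scales %s), %d training pixels, seed %d\n",
              length(x$coefficients) - 1L, paste(x$scales, collapse = ", "),
              x$n_train, x$seed))
  invisible(x)
}

#' Per-pixel foreground probability map
#'
#' Applies a trained [train_pixel_classifier()] model to an image,
#' returning the logistic foreground probability of every pixel.
#'
#' @param image Numeric matrix.
#' @param model A `pixel_classifier`.
#' @return Numeric matrix of probabilities in `[0, 1]`, same shape as
#'   `image`.
#' @export
pixel_probability_map <- function(image, model) {
  if (!inherits(model, "pixel_classifier")) {
    stop_chemotax("`model` must be a trained pixel_classifier")
  }
  x <- feature_matrix(image, model$scales)
  xs <- sweep(sweep(x, 2, model$feature_mean), 2, model$feature_sd, "/")
  eta <- drop(cbind(1, xs) %*% model$coefficients)
  matrix(stats::plogis((model$sharpness %||% 1) * eta),
         nrow(image), ncol(image))
}

#' Serialize a pixel classifier to JSON
#' @param model A `pixel_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pixel classifier from JSON
#' @param path Path written by [write_classifier_json()].
#' @return A `pixel_classifier`.
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(scales = as.double(obj$scales),
         coefficients = unlist(obj$coefficients),
         feature_mean = unlist(obj$feature_mean),
         feature_sd = unlist(obj$feature_sd),
         sharpness = as.double(obj$sharpness %||% 1),
         n_train = as.integer(obj$n_train), seed = as.integer(obj$seed)),
    class = "pixel_classifier"
  )
}
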