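#' Gram matrix of a feature map
#'
#' The channel-by-channel inner-product matrix of a feature map, summed over
#' all spatial positions: `G[i, j] = sum_p F[i, p] * F[j, p]`. Being a sum
#' over positions it is invariant to spatial rearrangement, which is what
#' makes it a texture (style) statistic. The raw sum is stored
#' (`normalize = "none"`); normalization of the style distance is handled in
#' [total_loss()].
#'
#' @param features an `H' x W' x C` activation array (as produced by
#'   [extract_features()]) or an `M x C` matrix of `M` positions.
#' @param layer optional layer name recorded on the result.
#' @param normalize `"none"` (raw sum, default) or `"positions"` (divide by
#'   the number of spatial positions `M`).
#' @return An object of class `gram_matrix`: list with `values` (`C x C`
#'   symmetric positive semidefinite matrix), `layer`, `n_channels`,
#'   `n_positions`.
#' @export
gram_matrix <- function(features, layer = NULL,
                        normalize = c("none", "positions")) {
  normalize <- match.arg(normalize)
  if (is.array(features) && length(dim(features)) == 3L) {
    d <- dim(features)
    f <- matrix(features, nrow = d[1] * d[2], ncol = d[3])
  } else if (is.matrix(features)) {
    f <- features
  } else {
    abort("`features` must be an H' x W' x C array or an M x C matrix",
          class = "hestain_format_error")
  }
  if (!all(is.finite(f))) {
    abort("feature map contains non-finite values", class = "hestain_numeric_error")
  }
  m <- nrow(f); cc <- ncol(f)
  g <- crossprod(f)
  if (normalize == "positions") g <- g / m
  structure(list(values = g, layer = layer, n_channels = cc, n_positions = m,
                 normalize = normalize),
            class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix> %d x %d (layer %s, %d positions)\n",
              x$n_channels, x$n_channels, x$layer %||% "?", x$n_positions))
  invisible(x)
}

#' Content representation of an image
#'
#' The activations at the designated content layer, unchanged. Deep-layer
#' activations retain the arrangement of structures in the image while
#' discarding exact pixel values, which is why matching them preserves
#' content.
#'
#' @param fm a `feature_map_set` from [extract_features()].
#' @param spec a [backbone_spec()].
#' @return An object of class `content_representation`.
#' @export
content_representation <- function(fm, spec = backbone_spec()) {
  act <- fm[[spec$content_layer]]
  if (is.null(act)) {
    abort(sprintf("content layer '%s' not present in feature map set (has: %s)",
                  spec$content_layer, paste(names(fm), collapse = ", ")),
          class = "hestain_config_error")
  }
  structure(list(activations = act, layer = spec$content_layer),
            class = "content_representation")
}

#' Style representation of an image
#'
#' The ordered list of Gram matrices at the style layers (shallow to deep).
#'
#' @inheritParams content_representation
#' @return An object of class `style_representation`: list of `gram_matrix`
#'   objects in `spec$style_layers` order.
#' @export
style_representation <- function(fm, spec = backbone_spec()) {
  missing <- setdiff(spec$style_layers, names(fm))
  if (length(missing)) {
    abort(sprintf("style layer(s) %s not present in feature map set",
                  paste(missing, collapse = ", ")),
          class = "hestain_config_error")
  }
  grams <- lapply(spec$style_layers, function(ly) gram_matrix(fm[[ly]], layer = ly))
  structure(list(grams = grams, layers = spec$style_layers),
            class = "style_representation")
}

#' Loss weights for style transfer
#'
#' @param alpha non-negative weight of the style loss relative to the content
#'   loss (default 100).
#' @param layer_weights non-negative per-layer style weights `w_i`, one per
#'   style layer (default 0.2 each for five layers).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 100, layer_weights = rep(0.2, 5)) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(layer_weights), all(layer_weights >= 0))
  structure(list(alpha = alpha, layer_weights = layer_weights),
            class = "loss_weights")
}

# squared-error style distance for one layer with the classical 1/(4 C^2 M^2)
# normalization; "mse" divides the squared difference by C^2 instead
style_layer_distance <- function(g_target, g_source, style_norm) {
  cc <- g_target$n_channels; m <- g_target$n_positions
  ss <- sum((g_target$values - g_source$values)^2)
  switch(style_norm,
         classic = ss / (4 * cc^2 * m^2),
         mse = ss / cc^2)
}

#' Composite content-plus-style loss
#'
#' `L = D_c(C_source, C_target) + alpha * sum_i w_i * D_s(S_source_i,
#' S_target_i)` with squared-error distances: the content term is
#' `0.5 * ||C_target - C_source||^2` and the per-layer style term is
#' `||G_target - G_source||^2 / (4 C^2 M^2)` (`style_norm = "classic"`).
#' The loss is zero exactly when the target representations equal both
#' source representations.
#'
#' @param c_target,c_source `content_representation`s of the target and the
#'   content (CLE) image.
#' @param s_target,s_source `style_representation`s of the target and the
#'   style (H&E) image.
#' @param weights a [loss_weights()].
#' @param style_norm `"classic"` (default) or `"mse"` normalization of the
#'   style distance.
#' @return A list with `total`, `content`, `style` (the alpha-weighted style
#'   sum), and `per_layer` style distances.
#' @export
total_loss <- function(c_target, c_source, s_target, s_source,
                       weights = loss_weights(),
                       style_norm = c("classic", "mse")) {
  style_norm <- match.arg(style_norm)
  if (!identical(dim(c_target$activations), dim(c_source$activations))) {
    abort(sprintf("content activation shapes differ at layer '%s'",
                  c_target$layer), class = "hestain_dimension_error")
  }
  n_layers <- length(s_target$grams)
  if (length(s_source$grams) != n_layers ||
      length(weights$layer_weights) != n_layers) {
    abort("style representations and layer weights must have equal length",
          class = "hestain_dimension_error")
  }
  content <- 0.5 * sum((c_target$activations - c_source$activations)^2)
  per_layer <- numeric(n_layers)
  for (i in seq_len(n_layers)) {
    gt <- s_target$grams[[i]]; gs <- s_source$grams[[i]]
    if (gt$n_channels != gs$n_channels) {
      abort(sprintf("Gram dimensions differ at layer '%s'", gt$layer %||% i),
            class = "hestain_dimension_error")
    }
    per_layer[i] <- style_layer_distance(gt, gs, style_norm)
  }
  style <- weights$alpha * sum(weights$layer_weights * per_layer)
  list(total = content + style, content = content, style = style,
       per_layer = per_layer)
}

#' Style-transfer configuration
#'
#' @param spec a [backbone_spec()] naming content and style layers.
#' @param weights a [loss_weights()] (defaults: alpha 100, five layer weights
#'   of 0.2).
#' @param n_iterations L-BFGS iteration budget (default 1600, the production
#'   setting).
#' @param init target initialization: `"content"` (copy of the content image;
#'   deterministic, content term starts at zero) or `"noise"` (uniform noise
#'   from `init_seed`).
#' @param init_seed seed for noise initialization.
#' @param style_norm style-distance normalization, see [total_loss()].
#' @param lbfgs_memory number of L-BFGS correction pairs retained.
#' @return An object of class `transfer_config`.
#' @export
transfer_config <- function(spec = backbone_spec(),
                            weights = loss_weights(),
                            n_iterations = 1600L,
                            init = c("content", "noise"),
                            init_seed = 0L,
                            style_norm = c("classic", "mse"),
                            lbfgs_memory = 20L) {
  init <- match.arg(init)
  style_norm <- match.arg(style_norm)
  stopifnot(n_iterations >= 1L)
  if (length(weights$layer_weights) != length(spec$style_layers)) {
    abort("one layer weight per style layer is required",
          class = "hestain_config_error")
  }
  structure(list(spec = spec, weights = weights,
                 n_iterations = as.integer(n_iterations), init = init,
                 init_seed = as.integer(init_seed), style_norm = style_norm,
                 lbfgs_memory = as.integer(lbfgs_memory)),
            class = "transfer_config")
}

# loss + gradient w.r.t. pixels at one parameter vector
transfer_objective <- function(par, h, w, backbone, cfg, c_source, s_grams_source,
                               record_layers) {
  x <- matrix(par, nrow = h * w, ncol = 3L)
  pp <- backbone$preprocess
  xp <- sweep(sweep(x, 2L, pp$mean, "-"), 2L, pp$sd, "/")
  fw <- net_forward(backbone$layers, xp, h, w, record = record_layers,
                    keep_cache = TRUE)
  cap <- fw$captured
  wts <- cfg$weights
  inject <- list()

  f_c <- cap[[cfg$spec$content_layer]]
  c_src_mat <- c_source  # M x C matrix
  d_content <- f_c - c_src_mat
  content <- 0.5 * sum(d_content^2)
  inject[[cfg$spec$content_layer]] <- d_content

  per_layer <- numeric(length(cfg$spec$style_layers))
  style <- 0
  for (i in seq_along(cfg$spec$style_layers)) {
    ly <- cfg$spec$style_layers[[i]]
    f <- cap[[ly]]
    m <- nrow(f); cc <- ncol(f)
    g_t <- crossprod(f)
    dg <- g_t - s_grams_source[[i]]
    e_i <- switch(cfg$style_norm,
                  classic = sum(dg^2) / (4 * cc^2 * m^2),
                  mse = sum(dg^2) / cc^2)
    per_layer[i] <- e_i
    coef <- wts$alpha * wts$layer_weights[i] *
      switch(cfg$style_norm, classic = 1 / (cc^2 * m^2), mse = 2 / cc^2)
    grad_f <- coef * (f %*% dg)
    inject[[ly]] <- if (is.null(inject[[ly]])) grad_f else inject[[ly]] + grad_f
    style <- style + wts$layer_weights[i] * e_i
  }
  style <- wts$alpha * style
  total <- content + style

  gx <- net_backward(fw$cache, inject)
  gpix <- sweep(gx, 2L, pp$sd, "/")
  list(total = total, content = content, style = style,
       grad = as.numeric(gpix))
}

#' Transfer the style of one image onto the content of another
#'
#' Runs pixel-space style transfer: the target image starts from the content
#' image (or seeded noise), and L-BFGS-B updates its pixels to minimize
#' [total_loss()] while the backbone weights stay fixed. Pixels are kept in
#' `[0, 1]` through box constraints. The style image is resized (bilinear) to
#' the content image's resolution before its Gram representation is captured,
#' since Gram statistics are resolution-sensitive.
#'
#' @param content_img structure-donating [stain_image()] (e.g. a CLE frame).
#' @param style_img appearance-donating [stain_image()] (e.g. an H&E
#'   micrograph).
#' @param backbone a `stain_backbone` exposing the configured layers.
#' @param cfg a [transfer_config()].
#' @return An object of class `style_transfer`: list with `image` (the
#'   stylized [stain_image()]), `trace` (tibble of recorded iterates:
#'   `iterate`, `evaluation`, `total`, `content`, `style` — the
#'   strictly-improving subsequence of function evaluations, non-increasing
#'   by construction), `evaluations` (every function evaluation), `initial`
#'   and `final` loss breakdowns, and `convergence` from the optimizer.
#' @export
stylize <- function(content_img, style_img, backbone, cfg = transfer_config()) {
  stopifnot(is_stain_image(content_img), is_stain_image(style_img))
  record_layers <- union(cfg$spec$content_layer, cfg$spec$style_layers)
  check_layers_registered(backbone, record_layers)

  h <- image_height(content_img); w <- image_width(content_img)
  style_rs <- resize_image(style_img, h, w)

  fm_c <- extract_features(content_img, backbone, layers = cfg$spec$content_layer)
  fm_s <- extract_features(style_rs, backbone, layers = cfg$spec$style_layers)
  c_src <- fm_c[[cfg$spec$content_layer]]
  c_src_mat <- matrix(c_src, nrow = dim(c_src)[1] * dim(c_src)[2])
  s_grams <- lapply(cfg$spec$style_layers, function(ly) {
    f <- fm_s[[ly]]
    crossprod(matrix(f, nrow = dim(f)[1] * dim(f)[2]))
  })

  par0 <- if (cfg$init == "content") {
    as.numeric(unclass(content_img))
  } else {
    run_with_preserved_rng(cfg$init_seed, runif(h * w * 3L))
  }

  ev <- new.env(parent = emptyenv())
  ev$log <- vector("list", 0L)
  ev$last_par_sum <- NA_real_
  ev$last <- NULL
  evaluate <- function(par) {
    s <- sum(par)
    if (!identical(s, ev$last_par_sum) || is.null(ev$last) ||
        !identical(par, ev$last_par)) {
      res <- transfer_objective(par, h, w, backbone, cfg, c_src_mat, s_grams,
                                record_layers)
      if (!is.finite(res$total)) {
        abort(sprintf(
          "non-finite loss at evaluation %d (total %g, content %g, style %g)",
          length(ev$log) + 1L, res$total, res$content, res$style),
          class = "hestain_numeric_error")
      }
      ev$last <- res
      ev$last_par <- par
      ev$last_par_sum <- s
      ev$log[[length(ev$log) + 1L]] <-
        c(total = res$total, content = res$content, style = res$style)
    }
    ev$last
  }

  opt <- optim(par0,
               fn = function(p) evaluate(p)$total,
               gr = function(p) evaluate(p)$grad,
               method = "L-BFGS-B", lower = 0, upper = 1,
               control = list(maxit = cfg$n_iterations,
                              lmm = cfg$lbfgs_memory,
                              factr = 1e2, pgtol = 0))

  evals <- dplyr::bind_rows(lapply(seq_along(ev$log), function(i) {
    tibble::tibble(evaluation = i,
                   total = ev$log[[i]][["total"]],
                   content = ev$log[[i]][["content"]],
                   style = ev$log[[i]][["style"]])
  }))
  improving <- evals$total < c(Inf, cummin(evals$total))[seq_len(nrow(evals))]
  improving[1] <- TRUE
  trace <- evals[improving, , drop = FALSE]
  if (nrow(trace) > cfg$n_iterations && cfg$n_iterations >= 2L) {
    # keep the initial point plus the most recent iterates within budget
    keep <- c(1L, seq(nrow(trace) - cfg$n_iterations + 2L, nrow(trace)))
    trace <- trace[keep, , drop = FALSE]
  }
  trace$iterate <- seq_len(nrow(trace)) - 1L
  trace <- trace[, c("iterate", "evaluation", "total", "content", "style")]

  target <- stain_image(array(pmin(pmax(opt$par, 0), 1), dim = c(h, w, 3L)),
                        source_id = paste0(attr(content_img, "source_id"),
                                           "_stylized"))
  structure(list(image = target,
                 trace = tibble::as_tibble(trace),
                 evaluations = evals,
                 initial = as.list(evals[1, c("total", "content", "style")]),
                 final = as.list(trace[nrow(trace), c("total", "content", "style")]),
                 convergence = opt$convergence,
                 message = opt$message,
                 config = cfg),
            class = "style_transfer")
}

#' @export
print.style_transfer <- function(x, ...) {
  cat(sprintf("<style_transfer> %d x %d px; loss %.4g -> %.4g over %d recorded iterates\n",
              image_height(x$image), image_width(x$image),
              x$initial$total, x$final$total, nrow(x$trace)))
  invisible(x)
}

#' @method tidy style_transfer
#' @export
tidy.style_transfer <- function(x, ...) x$trace

#' @method glance style_transfer
#' @export
glance.style_transfer <- function(x, ...) {
  tibble::tibble(initial_loss = x$initial$total, final_loss = x$final$total,
                 initial_content = x$initial$content,
                 final_content = x$final$content,
                 initial_style = x$initial$style, final_style = x$final$style,
                 n_iterates = nrow(x$trace), n_evaluations = nrow(x$evaluations),
                 convergence = x$convergence)
}

#' @method autoplot style_transfer
#' @export
autoplot.style_transfer <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("total", "content", "style"),
                            names_to = "term", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iterate, y = .data$loss,
                                   color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "recorded iterate", y = "loss (log scale)", color = NULL)
}
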