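# Plan-view height-template heading classifier --------------------------------
#
# A person standing upright leaves a characteristic patch in the plan-view
# height map; its shape (elliptical trunk cross-section, head offset toward
# the ventral side) depends on the heading. A 21x21-cell window centred on
# the person, normalized by its maximum height, plus the normalization
# constant and the count of occupied cells (443 attributes in total) feeds a
# 443-25-8 feed-forward network trained by classic back-propagation with
# symmetric sigmoid (tanh) units; the eight classes encode headings
# 0, 45, ..., 315 degrees in the tracking frame.

TEMPLATE_SIZE <- 21L

#' Extract a normalized plan-view height template
#'
#' A `21 x 21` cell window centred on the person's cell. Cells outside the
#' connected component overlapping the window centre are zeroed, heights are
#' divided by the window maximum (stored as the normalization constant), and
#' the number of surviving nonzero cells is recorded.
#'
#' @param maps A `"plan_view_maps"`.
#' @param center Length-2 position (tracking frame, m) of the person.
#' @return List of class `"height_template"`: `values` (21x21, in `[0, 1]`),
#'   `norm_constant` (m) and `nonzero_count`. An empty neighbourhood yields
#'   the all-zero template with `norm_constant = 0`.
#' @export
extract_height_template <- function(maps, center) {
  half <- (TEMPLATE_SIZE - 1L) %/% 2L
  ic <- as.integer(floor((center[1] - maps$x0) / maps$cell)) + 1L
  jc <- as.integer(floor((center[2] - maps$y0) / maps$cell)) + 1L
  if (ic < 1L || ic > maps$nx || jc < 1L || jc > maps$ny) {
    stop("template centre outside the map bounds", call. = FALSE)
  }
  vals <- matrix(0, TEMPLATE_SIZE, TEMPLATE_SIZE)
  ii <- (ic - half):(ic + half)
  jj <- (jc - half):(jc + half)
  ok_i <- ii >= 1L & ii <= maps$nx
  ok_j <- jj >= 1L & jj <= maps$ny
  vals[ok_i, ok_j] <- maps$height[ii[ok_i], jj[ok_j]]
  if (any(vals > 0)) {
    # keep only the connected component overlapping the centre 3x3 block
    lab <- EBImage::bwlabel(vals > 0)
    cb <- lab[(half):(half + 2L), (half):(half + 2L)]
    keep <- unique(cb[cb > 0])
    if (length(keep)) {
      vals[!(lab %in% keep)] <- 0
    } else {
      # fall back to the largest component (person slightly off-centre)
      sizes <- tabulate(lab[lab > 0])
      vals[lab != which.max(sizes)] <- 0
    }
  }
  nc <- max(vals)
  nz <- sum(vals > 0)
  if (nc > 0) vals <- vals / nc
  structure(list(values = vals, norm_constant = nc, nonzero_count = nz),
            class = "height_template")
}

#' Flatten a height template into the 443-attribute feature vector
#'
#' @param template A `"height_template"`.
#' @return Numeric vector: 441 normalized pixel values (column-major), the
#'   height normalization constant (m) and the nonzero-cell count.
#' @export
template_features <- function(template) {
  c(as.numeric(template$values), template$norm_constant, template$nonzero_count)
}

# forward pass: X is n x 443 already standardized
.nn_forward <- function(model, Xs) {
  H <- tanh(sweep(Xs %*% model$W1, 2, model$b1, "+"))
  O <- tanh(sweep(H %*% model$W2, 2, model$b2, "+"))
  list(H = H, O = O)
}

.nn_standardize <- function(model, X) {
  sweep(sweep(X, 2, model$center), 2, model$scale, "/")
}

#' Train the 443-25-8 heading classifier
#'
#' Classic back-propagation (mini-batch stochastic gradient descent on mean
#' squared error) with symmetric sigmoid (tanh) activations and one-hot
#' targets in `{-1, +1}`. Features are standardized internally (the scaling
#' is stored in the model). Training is deterministic given the seed.
#'
#' @param features n x 443 matrix of template feature vectors.
#' @param labels Integer classes in 0..7 (heading = class x 45 degrees).
#' @param hidden Hidden layer width.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch Mini-batch size.
#' @param seed Seed for initialization and shuffling.
#' @return List of class `"heading_classifier"`.
#' @export
train_heading_classifier <- function(features, labels, hidden = 25L,
                                     epochs = 200L, lr = 0.01, batch = 32L,
                                     seed = 1L) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (!nrow(X)) stop("empty training set", call. = FALSE)
  if (any(y < 0L | y > 7L)) stop("labels must be in 0..7", call. = FALSE)
  if (length(setdiff(0:7, unique(y)))) {
    warning("not all 8 heading classes are represented in the training data")
  }
  d <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-9] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Tmat <- matrix(-1, nrow(X), 8L)
  Tmat[cbind(seq_len(nrow(X)), y + 1L)] <- 1
  set.seed(seed)
  W1 <- matrix(rnorm(d * hidden, 0, sqrt(1 / d)), d, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(rnorm(hidden * 8L, 0, sqrt(1 / hidden)), hidden, 8L)
  b2 <- rep(0, 8L)
  n <- nrow(Xs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batch)) {
      idx <- ord[s:min(s + batch - 1L, n)]
      Xb <- Xs[idx, , drop = FALSE]
      Tb <- Tmat[idx, , drop = FALSE]
      H <- tanh(sweep(Xb %*% W1, 2, b1, "+"))
      O <- tanh(sweep(H %*% W2, 2, b2, "+"))
      dO <- (O - Tb) * (1 - O^2)             # dMSE/dpreact, up to 2/n
      dH <- (dO %*% t(W2)) * (1 - H^2)
      m <- length(idx)
      W2 <- W2 - lr * t(H) %*% dO / m
      b2 <- b2 - lr * colSums(dO) / m
      W1 <- W1 - lr * t(Xb) %*% dH / m
      b1 <- b1 - lr * colSums(dH) / m
    }
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 center = ctr, scale = scl,
                 meta = list(hidden = hidden, epochs = epochs, lr = lr,
                             batch = batch, seed = seed, n_train = n)),
            class = "heading_classifier")
}

#' Classify a height template
#'
#' The class is the output neuron with the maximum activation (ties broken
#' by the lowest index); the heading is `class x 45` degrees in the tracking
#' frame; the quality score maps the winning activation from `[-1, 1]` to
#' `[0, 1]`. An all-zero template is classified with quality 0.
#'
#' @param model A `"heading_classifier"`.
#' @param template A `"height_template"` or a 443-long feature vector.
#' @return List with `class` (0..7), `heading` (degrees) and `quality`
#'   (in `[0, 1]`).
#' @export
classify_heading <- function(model, template) {
  x <- if (inherits(template, "height_template")) template_features(template)
       else as.numeric(template)
  out <- predict_heading(model, matrix(x, 1))
  if (inherits(template, "height_template") && template$nonzero_count == 0L) {
    out$quality <- 0
  }
  list(class = out$class[1], heading = out$heading[1], quality = out$quality[1])
}

#' Batch heading predictions
#'
#' @param model A `"heading_classifier"`.
#' @param features n x 443 feature matrix.
#' @return Tibble with `class`, `heading`, `quality` and the raw output in
#'   attribute `outputs`.
#' @export
predict_heading <- function(model, features) {
  Xs <- .nn_standardize(model, as.matrix(features))
  O <- .nn_forward(model, Xs)$O
  cls <- max.col(O, ties.method = "first") - 1L
  out <- tibble(
    class = cls,
    heading = cls * 45,
    quality = (O[cbind(seq_len(nrow(O)), cls + 1L)] + 1) / 2
  )
  attr(out, "outputs") <- O
  out
}

#' Static heading from a temporally consistent classifier stream
#'
#' Emits the class heading on every frame where the same class has held with
#' quality above the threshold for at least `k_frames` consecutive frames;
#' any class change, quality drop or missing frame resets the counter.
#'
#' @param class Integer vector of per-frame classes (NA = no classification).
#' @param quality Numeric vector of per-frame quality scores.
#' @param q_threshold Quality threshold.
#' @param k_frames Required run length.
#' @return Numeric vector of static headings (degrees; NA where
#'   unconfirmed).
#' @export
confirm_static_heading <- function(class, quality, q_threshold = 0.8,
                                   k_frames = 3L) {
  n <- length(class)
  out <- rep(NA_real_, n)
  run <- 0L
  prev <- NA_integer_
  for (i in seq_len(n)) {
    ok <- !is.na(class[i]) && !is.na(quality[i]) && quality[i] > q_threshold
    if (ok && !is.na(prev) && class[i] == prev) {
      run <- run + 1L
    } else if (ok) {
      run <- 1L
    } else {
      run <- 0L
    }
    prev <- if (ok) class[i] else NA_integer_
    if (run >= k_frames) out[i] <- class[i] * 45
  }
  out
}

#' Serialize / restore a trained classifier as JSON text
#'
#' @param model A `"heading_classifier"`.
#' @param path File path.
#' @return `read_heading_classifier()` returns the model.
#' @export
write_heading_classifier <- function(model, path) {
  obj <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              center = model$center, scale = model$scale, meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_heading_classifier
#' @export
read_heading_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
                 W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2),
                 center = as.numeric(obj$center), scale = as.numeric(obj$scale),
                 meta = obj$meta),
            class = "heading_classifier")
}

#' Generate a labelled height-template dataset from synthetic bodies
#'
#' Renders bodies standing at grid positions across the camera coverage at
#' the eight principal tracking-frame orientations, runs the plan-view
#' pipeline (background subtraction against the known floor, map
#' construction) and extracts one labelled template per render.
#'
#' @param bodies List of `"body_model"` objects; the standard setup uses
#'   four trainer bodies of different heights.
#' @param cam A `"depth_camera"`.
#' @param positions Optional n x 2 matrix of tracking-frame positions; the
#'   default covers the usable range on a regular grid.
#' @param config A `"sim_config"` (cell size, cut-off, depth noise).
#' @param repeats Renders per (body, position, class); noise differs.
#' @param jitter_deg Heading jitter around each class centre (uniform
#'   half-width, degrees).
#' @return Tibble with 443 feature columns `f1..f443`, `label` (0..7) and
#'   bookkeeping columns.
#' @export
generate_template_dataset <- function(bodies, cam, positions = NULL,
                                      config = sim_config(), repeats = 1L,
                                      jitter_deg = 0) {
  frame <- camera_tracking_frame(cam, config$north_deg)
  if (is.null(positions)) {
    # 0.5 m grid over the camera's usable coverage; positions outside the
    # frustum render no person and are skipped automatically
    gx <- seq(-2.5, 2.5, by = 0.5)
    gy <- seq(2.0, 5.5, by = 0.5)
    positions <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))
  }
  floor_bg <- floor_depth_image(cam)
  bounds <- c(-3.2, 3.2, 0.5, 6.2)
  rows <- list()
  rot <- cam$yaw_deg - 90  # tracking-frame heading -> world heading offset
  for (bi in seq_along(bodies)) {
    body <- bodies[[bi]]
    for (pi in seq_len(nrow(positions))) {
      pw <- from_tracking(frame, c(positions[pi, 1], positions[pi, 2], 0))
      for (cls in 0:7) {
        for (r in seq_len(repeats)) {
          h_track <- cls * 45 + if (jitter_deg > 0) runif(1, -jitter_deg, jitter_deg) else 0
          fr <- render_depth_frame(body, c(pw[1], pw[2], wrap_heading(h_track + rot)),
                                   cam, floor_bg, config$depth_noise_coef)
          fg <- subtract_background(fr$depth, floor_bg, tau = 0.10)
          idx <- which(fg)
          if (!length(idx)) next
          vv <- (idx - 1L) %% cam$height
          uu <- (idx - 1L) %/% cam$height
          Pt <- .shift_from_camera(
            to_tracking(frame, backproject_pixels(cam, uu, vv, fr$depth[idx])),
            config$surface_offset)
          w <- (fr$depth[idx] / 1000)^2 / (cam$fx * cam$fy * config$cell^2)
          maps <- build_plan_view_maps(Pt, cell = config$cell,
                                       cutoff = config$height_cutoff,
                                       bounds = bounds, weights = w)
          cells <- .occupied_cells(maps)
          if (is.null(cells)) next
          ctr <- c(sum(cells[, "x"] * cells[, "occ"]), sum(cells[, "y"] * cells[, "occ"])) /
            sum(cells[, "occ"])
          tpl <- extract_height_template(maps, ctr)
          if (tpl$nonzero_count == 0L) next
          rows[[length(rows) + 1L]] <- c(template_features(tpl), cls, bi, pi)
        }
      }
    }
  }
  M <- do.call(rbind, rows)
  colnames(M) <- c(paste0("f", 1:443), "label", "body", "position")
  out <- as_tibble(M)
  out$label <- as.integer(out$label)
  out
}

#' Read / write template datasets as CSV
#'
#' @param data Tibble from [generate_template_dataset()].
#' @param path File path.
#' @return `read_template_csv()` returns a tibble.
#' @export
write_template_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_template_csv
#' @export
read_template_csv <- function(path) readr::read_csv(path, show_col_types = FALSE)
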