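# Desk-scale segmentation training harness: patient-level 14:1:1 split,
# hybrid Dice + cross-entropy loss, class-imbalance sampler, polar
# augmentations, and a compact pixelwise classifier trained with Adam.
#
# The trainable model is a small multinomial MLP over per-pixel radial-profile
# features of the lumen-centered polar image (no deep-learning framework is
# available here); the measurable contract of the harness — split hygiene,
# loss behaviour, balancing, augmentation invariants, held-out Dice — is
# independent of the backbone.

SEG_CLASSES <- c("background", "lumen", "wall", "lipid", "calcium")

#' Patient-level train/test/validation split
#'
#' Random, deterministic given `seed`, at a 14:1:1 patient ratio. No patient
#' appears in two partitions. With fewer than 16 patients the ratio is
#' rounded proportionally with at least one patient per partition.
#'
#' @param patient_ids character or integer vector of unique patient ids.
#' @param seed integer.
#' @param ratio train:test:validation ratio (default `c(14, 1, 1)`).
#' @return list: `train`, `test`, `validation`, `seed`.
#' @export
patient_split <- function(patient_ids, seed = 1, ratio = c(14, 1, 1)) {
  ids <- unique(patient_ids)
  n <- length(ids)
  if (n < 3) stop("need at least 3 patients for a 3-way split")
  shuffled <- with_local_seed(seed, sample(ids))
  target <- n * ratio / sum(ratio)
  n_test <- max(1L, round(target[2]))
  n_val <- max(1L, round(target[3]))
  n_train <- n - n_test - n_val
  stopifnot(n_train >= 1)
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[n_train + seq_len(n_test)]),
       validation = sort(shuffled[n_train + n_test + seq_len(n_val)]),
       seed = seed)
}

#' Dice overlap of one class between two masks
#'
#' 2|A∩B| / (|A|+|B|); both-empty convention: 1.
#'
#' @param pred,truth equally sized label matrices/vectors.
#' @param class the label value compared.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(pred, truth, class) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth must have identical shape")
  }
  a <- pred == class
  b <- truth == class
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Hybrid Dice + cross-entropy loss
#'
#' `total = mean_c(1 - softDice_c) + mean_i(-log p_i[truth_i])`, equal
#' weighting. Soft Dice per class uses predicted probabilities against
#' one-hot truth; classes absent from both prediction mass and truth are
#' counted as Dice 1.
#'
#' @param prob N x C matrix of per-pixel class probabilities (rows sum to 1).
#' @param truth integer vector of true class indices (1..C).
#' @param dice_weight,ce_weight term weights (default 1 and 1).
#' @return list: `dice_term` (per class soft Dice), `ce_term`, `total`.
#' @export
hybrid_loss <- function(prob, truth, dice_weight = 1, ce_weight = 1) {
  n <- nrow(prob); C <- ncol(prob)
  stopifnot(length(truth) == n, all(truth >= 1), all(truth <= C))
  if (max(abs(rowSums(prob) - 1)) > 1e-6 || any(prob < -1e-12)) {
    stop("probabilities must be non-negative and normalized per pixel")
  }
  t_onehot <- matrix(0, n, C)
  t_onehot[cbind(seq_len(n), truth)] <- 1
  s <- colSums(prob * t_onehot)
  u <- colSums(prob) + colSums(t_onehot)
  dice <- ifelse(u == 0, 1, 2 * s / u)
  ce <- -mean(log(pmax(prob[cbind(seq_len(n), truth)], 1e-12)))
  list(dice_term = dice, ce_term = ce,
       total = dice_weight * mean(1 - dice) + ce_weight * ce)
}

#' Class-balancing frame sampler
#'
#' Frames are weighted by the inverse frequency of the rarest tissue class
#' they contain (frames containing none of the tracked classes form their own
#' stratum), so that per-epoch draws of minority-class frames approach the
#' majority rate. Classes absent from the whole set are excluded with a
#' warning.
#'
#' @param presence logical matrix, frames x tracked classes.
#' @param seed kept for a stable call signature (weights are deterministic).
#' @return numeric frame weights summing to 1.
#' @export
balanced_sampler <- function(presence, seed = 1) {
  presence <- as.matrix(presence)
  n <- nrow(presence)
  if (n == 1) return(1)
  counts <- colSums(presence)
  if (any(counts == 0)) {
    warning("class(es) absent from the whole set: ",
            paste(colnames(presence)[counts == 0], collapse = ", "))
    presence <- presence[, counts > 0, drop = FALSE]
    counts <- counts[counts > 0]
  }
  none <- rowSums(presence) == 0
  w <- numeric(n)
  if (length(counts) > 0) {
    inv <- 1 / counts
    w <- apply(presence, 1, function(row) {
      if (any(row)) max(inv[row]) else 0
    })
  }
  if (any(none)) w[none] <- 1 / sum(none)
  if (all(w == 0)) w <- rep(1, n)
  w / sum(w)
}

#' Circular shift of a polar frame along the angular axis
#' @param x matrix (angles in rows).
#' @param k shift in rows (positive or negative).
#' @return shifted matrix.
#' @export
roll_polar <- function(x, k) {
  n <- nrow(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  x[c((n - k + 1):n, 1:(n - k)), , drop = FALSE]
}

#' Random polar augmentation of an image/mask pair
#'
#' Horizontal rolling (circular shift along the angular axis) and flips are
#' applied identically to image and mask; intensity jitter (brightness and
#' contrast) touches the image only. All draws flow from `seed`.
#'
#' @param frame polar intensity matrix.
#' @param mask polar label matrix.
#' @param seed integer.
#' @return list: `frame`, `mask`, `ops` (the drawn parameters).
#' @export
augment_polar <- function(frame, mask, seed = 1) {
  stopifnot(identical(dim(frame), dim(mask)))
  ops <- with_local_seed(seed, list(
    roll = sample.int(nrow(frame), 1) - 1L,
    flip = stats::runif(1) < 0.5,
    gain = stats::runif(1, 0.95, 1.05),
    bias = stats::runif(1, -4, 4)
  ))
  f <- roll_polar(frame, ops$roll)
  m <- roll_polar(mask, ops$roll)
  if (ops$flip) {
    f <- f[rev(seq_len(nrow(f))), , drop = FALSE]
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  f <- pmin(pmax(f * ops$gain + ops$bias, 0), 255)
  list(frame = f, mask = m, ops = ops)
}

# map full class codes to the 5 training classes (1-based)
seg_class_of <- function(mask) {
  cls <- oct_classes()
  out <- matrix(1L, nrow(mask), ncol(mask))          # background
  out[mask == cls[["lumen"]]] <- 2L
  out[mask == cls[["wall"]] | mask == cls[["cap"]]] <- 3L
  out[mask == cls[["lipid"]]] <- 4L
  out[mask == cls[["calcium"]]] <- 5L
  out
}

#' Generate a polar phantom training set
#'
#' Each "patient" is a small phantom pullback with randomized lumen geometry
#' and plaque burden; frames are resampled to a lumen-centered polar grid
#' (`grid` angles x `grid` radii) with co-registered labels.
#'
#' @param n_patients number of phantom patients.
#' @param frames_per_patient frames per patient (default 2).
#' @param frame_size Cartesian phantom size (default 256).
#' @param grid polar grid side (default 128).
#' @param seed integer.
#' @return list of samples: `patient`, `image` (grid x grid, 0..255),
#'   `labels` (grid x grid, 1..5 per `SEG_CLASSES`).
#' @export
phantom_training_set <- function(n_patients = 12, frames_per_patient = 2,
                                 frame_size = 256, grid = 128, seed = 1) {
  specs <- with_local_seed(seed, lapply(seq_len(n_patients), function(p) {
    shape <- sample(c("circle", "ellipse", "perturbed"), 1)
    # every patient carries a lipid plaque; about half additionally carry a
    # calcium deposit (typical cohort prevalence), so both minority classes
    # are represented in any non-degenerate patient split
    tissues <- c("lipid", if (stats::runif(1) < 0.5) "calcium")
    centers <- stats::runif(1, 0, 360) + c(0, 180)
    plaques <- lapply(seq_along(tissues), function(j) {
      list(
        frame_interval = c(1, frames_per_patient),
        tissue = tissues[j],
        arc_center_deg = centers[j] %% 360,
        arc_span_deg = stats::runif(1, 60, 150),
        cap_thickness_px = sample(4:10, 1),
        depth_px = sample(20:32, 1)
      )
    })
    phantom_spec(
      n_frames = frames_per_patient, frame_size = frame_size,
      pixel_spacing_um = 10,
      lumen = list(shape = shape, radius_px = stats::runif(1, 45, 70),
                   eccentricity = stats::runif(1, 0.7, 0.95),
                   roughness = stats::runif(1, 0.02, 0.08)),
      wall_thickness_px = 45,
      plaques = plaques,
      speckle = list(enabled = TRUE, grain_px = 3, variance = 0.04),
      patient_id = sprintf("phantom%02d", p),
      seed = sample.int(1e6, 1)
    )
  }))
  samples <- list()
  for (sp in specs) {
    gen <- phantom_generate(sp)
    sz <- sp$frame_size
    center <- c((sz - 1) / 2, (sz - 1) / 2)
    max_r <- sqrt(2) * (sz - 1) / 2
    step <- max_r / grid
    for (f in seq_len(sp$n_frames)) {
      img <- to_polar(get_frame(gen$pullback, f), center, n_angles = grid,
                      n_radii = grid, radial_step_px = step)$values
      lab <- to_polar(gen$truth$masks[[f]], center, n_angles = grid,
                      n_radii = grid, radial_step_px = step,
                      interp = "nearest")$values
      samples[[length(samples) + 1]] <- list(
        patient = sp$patient_id, image = img,
        labels = seg_class_of(lab)
      )
    }
  }
  samples
}

# per-pixel features of a polar intensity image: radial profile window,
# angular context, normalized radius, cumulative mean, local radial sd.
# Intensities are standardized by the frame's bright-tissue level (95th
# percentile) so the features are invariant to per-frame gain.
polar_pixel_features <- function(img) {
  na <- nrow(img); nr <- ncol(img)
  bright <- stats::quantile(img, 0.95, names = FALSE)
  if (bright <= 0) bright <- 1
  x <- pmin(img / bright, 1.5)
  at <- function(o) x[, pmin(pmax(seq_len(nr) + o, 1L), nr), drop = FALSE]
  offs <- c(-12L, -8L, -5L, -3L, -1L, 0L, 1L, 3L, 5L, 8L, 12L)
  grad_offs <- c(-6L, -3L, 0L, 3L, 6L)
  n_extra <- 7L
  feats <- matrix(0, na * nr, length(offs) + length(grad_offs) + n_extra)
  j <- 0L
  for (o in offs) {
    j <- j + 1L
    feats[, j] <- as.vector(at(o))
  }
  # radial derivatives: border sharpness (sharp calcium vs diffuse lipid)
  for (o in grad_offs) {
    j <- j + 1L
    feats[, j] <- as.vector(at(o + 2L) - at(o - 2L))
  }
  # speckle-suppressed center intensity at two scales
  feats[, j + 1L] <- as.vector((at(-2L) + at(-1L) + x + at(1L) + at(2L)) / 5)
  feats[, j + 2L] <- as.vector((at(-5L) + at(-2L) + x + at(2L) + at(5L)) / 5)
  # angular context
  up <- x[c(2:na, 1), ]; dn <- x[c(na, 1:(na - 1)), ]
  feats[, j + 3L] <- as.vector((up + dn + x) / 3)
  # normalized radius
  feats[, j + 4L] <- rep((seq_len(nr) - 1) / (nr - 1), each = na)
  # cumulative mean from the center outward
  csum <- t(apply(x, 1, cumsum))
  feats[, j + 5L] <- as.vector(sweep(csum, 2, seq_len(nr), "/"))
  # local radial sd
  m1 <- (at(3L) + at(-3L) + x) / 3
  m2 <- (at(3L)^2 + at(-3L)^2 + x^2) / 3
  feats[, j + 6L] <- as.vector(sqrt(pmax(m2 - m1^2, 0)))
  # raw (non-standardized) center intensity
  feats[, j + 7L] <- as.vector(img / 255)
  feats
}

relu <- function(z) z * (z > 0)

mlp_forward <- function(w, X) {
  z1 <- sweep(X %*% w$W1, 2, w$b1, "+"); h1 <- relu(z1)
  z2 <- sweep(h1 %*% w$W2, 2, w$b2, "+"); h2 <- relu(z2)
  z3 <- sweep(h2 %*% w$W3, 2, w$b3, "+")
  z3 <- z3 - apply(z3, 1, max)
  e <- exp(z3)
  p <- e / rowSums(e)
  list(h1 = h1, h2 = h2, p = p)
}

# gradient of the hybrid loss wrt logits
hybrid_grad_logits <- function(p, truth) {
  n <- nrow(p); C <- ncol(p)
  t_onehot <- matrix(0, n, C)
  t_onehot[cbind(seq_len(n), truth)] <- 1
  g_ce <- (p - t_onehot) / n
  s <- colSums(p * t_onehot)
  u <- colSums(p) + colSums(t_onehot)
  live <- u > 0
  # d mean_c(1 - D_c) / dp_ic = -(2/C) (t_ic u_c - s_c) / u_c^2
  gd <- matrix(0, n, C)
  for (c in which(live)) {
    gd[, c] <- -(2 / C) * (t_onehot[, c] * u[c] - s[c]) / u[c]^2
  }
  inner <- rowSums(gd * p)
  g_dice <- p * (gd - inner)
  g_ce + g_dice
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train the desk-scale polar segmenter
#'
#' Pixelwise multinomial MLP over radial-profile features, trained with the
#' hybrid Dice + cross-entropy loss and the Adam optimizer (step-decay
#' learning rate), class-balanced frame sampling and polar augmentations.
#' Reports per-class Dice on the held-out (test + validation) patients.
#'
#' @param samples training set from [phantom_training_set()].
#' @param split [patient_split()] of the sample patients.
#' @param epochs training epochs (default 20).
#' @param seed integer; drives sampling and augmentation draws.
#@TMP
#' @param px_per_class pixels sampled per present class per step (default 120).
#' @param hidden hidden layer sizes (default `c(48, 24)`).
#' @param lr initial learning rate (default 0.01), halved every 8 epochs.
#' @param augment apply polar augmentations (default TRUE).
#' @param shuffle_labels permute the frame-label pairing of the training set
#'   (negative control; default FALSE).
#' @return object of class `oct_segmenter`: weights, `dice` (held-out
#'   per-class Dice), `history` (per-epoch training loss), `split`.
#' @export
train_segmenter <- function(samples, split, epochs = 20, seed = 7,
                            steps_per_epoch = 40, px_per_class = 120,
                            hidden = c(48, 24), lr = 0.01, augment = TRUE,
                            shuffle_labels = FALSE) {
  patients <- vapply(samples, function(s) s$patient, "")
  tr <- which(patients %in% split$train)
  ho <- which(patients %in% c(split$test, split$validation))
  if (length(tr) == 0 || length(ho) == 0) stop("empty partition")
  C <- length(SEG_CLASSES)
  n_feat <- ncol(polar_pixel_features(samples[[tr[1]]]$image))

  with_local_seed(seed, {
    if (shuffle_labels) {
      perm <- sample(tr)
      for (i in seq_along(tr)) {
        samples[[tr[i]]]$labels <- samples[[perm[i]]]$labels
      }
    }
    presence <- t(vapply(samples[tr], function(s) {
      c(lipid = any(s$labels == 4L), calcium = any(s$labels == 5L))
    }, logical(2)))
    wts <- suppressWarnings(balanced_sampler(presence))

    init <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    }
    w <- list(W1 = init(n_feat, hidden[1]), b1 = rep(0, hidden[1]),
              W2 = init(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
              W3 = init(hidden[2], C), b3 = rep(0, C))
    zeros <- lapply(w, function(x) x * 0)
    state <- list(w = w, m = zeros, v = zeros)
    history <- numeric(epochs)
    t_step <- 0

    for (ep in seq_len(epochs)) {
      lr_ep <- lr * 0.5^((ep - 1) %/% 8)
      ep_loss <- numeric(steps_per_epoch)
      for (st in seq_len(steps_per_epoch)) {
        si <- tr[sample.int(length(tr), 1, prob = wts)]
        s <- samples[[si]]
        if (augment) {
          aug <- augment_polar(s$image, s$labels,
                               seed = sample.int(1e6, 1))
          img <- aug$frame; lab <- aug$mask
        } else {
          img <- s$image; lab <- s$labels
        }
        feats <- polar_pixel_features(img)
        labv <- as.vector(lab)
        idx <- unlist(lapply(seq_len(C), function(c) {
          pool <- which(labv == c)
          if (length(pool) == 0) return(integer())
          pool[sample.int(length(pool), min(px_per_class, length(pool)))]
        }))
        X <- feats[idx, , drop = FALSE]
        y <- labv[idx]
        fwd <- mlp_forward(state$w, X)
        loss <- hybrid_loss(fwd$p, y)
        ep_loss[st] <- loss$total
        gz3 <- hybrid_grad_logits(fwd$p, y)
        gW3 <- t(fwd$h2) %*% gz3
        gb3 <- colSums(gz3)
        gh2 <- gz3 %*% t(state$w$W3) * (fwd$h2 > 0)
        gW2 <- t(fwd$h1) %*% gh2
        gb2 <- colSums(gh2)
        gh1 <- gh2 %*% t(state$w$W2) * (fwd$h1 > 0)
        gW1 <- t(X) %*% gh1
        gb1 <- colSums(gh1)
        t_step <- t_step + 1
        state <- adam_step(state, list(W1 = gW1, b1 = gb1, W2 = gW2,
                                       b2 = gb2, W3 = gW3, b3 = gb3),
                           lr_ep, t_step)
      }
      history[ep] <- stats::median(ep_loss)
    }

    model <- structure(list(weights = state$w, classes = SEG_CLASSES,
                            history = history, split = split),
                       class = "oct_segmenter")
    model$dice <- evaluate_segmenter(model, samples[ho])
    model
  })
}

#' Predict polar labels with a trained segmenter
#' @param object an `oct_segmenter`.
#' @param newdata polar intensity matrix.
#' @param ... unused.
#' @return integer label matrix (1..5 per `SEG_CLASSES`).
#' @export
predict.oct_segmenter <- function(object, newdata, ...) {
  feats <- polar_pixel_features(newdata)
  p <- mlp_forward(object$weights, feats)$p
  matrix(max.col(p, ties.method = "first"), nrow(newdata), ncol(newdata))
}

#' Held-out per-class Dice of a segmenter
#' @param model an `oct_segmenter`.
#' @param samples evaluation samples (as from [phantom_training_set()]).
#' @return named numeric vector: mean Dice for lumen, wall, lipid, calcium.
#' @export
evaluate_segmenter <- function(model, samples) {
  per <- sapply(samples, function(s) {
    pred <- predict(model, s$image)
    vapply(2:5, function(c) {
      if (!any(s$labels == c)) return(NA_real_)
      dice_score(pred, s$labels, c)
    }, 0)
  })
  out <- rowMeans(per, na.rm = TRUE)
  names(out) <- SEG_CLASSES[2:5]
  out
}

#' @export
print.oct_segmenter <- function(x, ...) {
  cat("polar MLP segmenter; held-out Dice:\n")
  print(round(x$dice, 3))
  invisible(x)
}
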