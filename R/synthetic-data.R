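#' Latent quality model for simulated pairwise preferences
#'
#' Bradley-Terry-type preference structure: each model carries a latent
#' clinical quality `q`, and an observer presented with models i and j
#' prefers i with probability `plogis(beta * (q_i - q_j))`. `beta` is the
#' observers' discrimination: 0 makes every choice a coin flip, large
#' values make the better model win almost surely.
#'
#' @param models Character vector of model tags.
#' @param qualities Numeric latent qualities, one per model.
#' @param beta Discrimination, >= 0. Default 3.
#' @return A `latent_quality_model` list.
#' @export
latent_quality_model <- function(models, qualities, beta = 3) {
  if (length(models) != length(qualities))
    stop("one quality per model required", call. = FALSE)
  if (anyDuplicated(models)) stop("duplicate model tags", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(models = models,
                 qualities = stats::setNames(qualities, models),
                 beta = beta),
            class = "latent_quality_model")
}

#' Probability that model i is preferred over model j
#' @param qm A [latent_quality_model()].
#' @param i,j Model tags.
#' @return Preference probability in (0, 1).
#' @export
preference_prob <- function(qm, i, j) {
  q <- qm$qualities
  if (!all(c(i, j) %in% names(q))) stop("unknown model tag", call. = FALSE)
  stats::plogis(qm$beta * (q[[i]] - q[[j]]))
}

#' Simulated observer panel
#'
#' @param n Number of observers.
#' @param accuracy Per-category probability of selecting a correct
#'   diagnosis (recycled over observers).
#' @param consistency Probability that a control answer repeats the
#'   original answer verbatim (1 = perfectly self-consistent).
#' @param na_prob Probability that a miss is recorded as "not applicable"
#'   rather than a wrong category.
#' @return Data frame with columns `observer_id`, `accuracy`,
#'   `consistency`, `na_prob`.
#' @export
simulated_observers <- function(n, accuracy = 0.45, consistency = 0.8,
                                na_prob = 0.1) {
  data.frame(observer_id = sprintf("obs%02d", seq_len(n)),
             accuracy = rep_len(accuracy, n),
             consistency = rep_len(consistency, n),
             na_prob = rep_len(na_prob, n),
             stringsAsFactors = FALSE)
}

disc_offsets <- function(radius) {
  d <- seq(-radius, radius)
  g <- expand.grid(dr = d, dc = d)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  list(dr = g$dr, dc = g$dc)
}

#' Simulate a branching vessel mask
#'
#' Draws connected, branching vessel-like structures by directed random
#' walks: trunks start at the image border heading inward, wander with
#' small angular diffusion, occasionally spawn thinner side branches, and
#' terminate at the border or after their step budget. The sparse branching
#' geometry keeps the vessel fraction low (typically a few percent to
#' ~10%), mirroring the class imbalance of real fundus masks.
#'
#' @param width,height Image size in pixels.
#' @param n_trunks Number of seed trunks started at the border.
#' @param branch_prob Per-step probability that a walker spawns a branch.
#' @param step_length Step length in pixels.
#' @param thickness Vessel radius in pixels (trunks; branches are thinner).
#' @param max_steps Step budget per trunk.
#' @param seed Integer seed; identical seeds give identical masks.
#' @return Integer 0/1 matrix with attribute `vessel_fraction`.
#' @export
simulate_vessel_mask <- function(width = 512L, height = 512L, n_trunks = 5L,
                                 branch_prob = 0.01, step_length = 1,
                                 thickness = 2L, max_steps = NULL,
                                 seed = NULL) {
  if (width < 8L || height < 8L)
    stop("mask must be at least 8x8 pixels", call. = FALSE)
  if (n_trunks < 1L) stop("need at least one trunk", call. = FALSE)
  if (is.null(max_steps)) max_steps <- round(1.2 * max(width, height))
  mask <- matrix(FALSE, height, width)
  with_seed(seed, {
    offs <- lapply(0:max(1L, thickness), disc_offsets)
    # walkers: list of (r, c, angle, radius, life)
    walkers <- lapply(seq_len(n_trunks), function(i) {
      side <- sample.int(4L, 1L)
      r <- switch(side, 1, height, sample.int(height, 1L), sample.int(height, 1L))
      c <- switch(side, sample.int(width, 1L), sample.int(width, 1L), 1, width)
      # aim roughly toward the image center
      ang <- atan2(height / 2 - r, width / 2 - c) + stats::rnorm(1, 0, 0.3)
      list(r = r, c = c, ang = ang, radius = thickness, life = max_steps)
    })
    max_walkers <- 8L * n_trunks
    n_spawned <- n_trunks
    while (length(walkers)) {
      wk <- walkers[[1L]]
      walkers <- walkers[-1L]
      while (wk$life > 0) {
        wk$ang <- wk$ang + stats::rnorm(1, 0, 0.12)
        wk$r <- wk$r + step_length * sin(wk$ang)
        wk$c <- wk$c + step_length * cos(wk$ang)
        if (wk$r < 1 || wk$r > height || wk$c < 1 || wk$c > width) break
        off <- offs[[max(1L, wk$radius) + 1L]]
        rr <- off$dr + round(wk$r)
        cc <- off$dc + round(wk$c)
        ok <- rr >= 1 & rr <= height & cc >= 1 & cc <= width
        mask[cbind(rr[ok], cc[ok])] <- TRUE  # in place: avoids per-step copies
        wk$life <- wk$life - 1L
        if (n_spawned < max_walkers && stats::runif(1) < branch_prob) {
          n_spawned <- n_spawned + 1L
          walkers[[length(walkers) + 1L]] <- list(
            r = wk$r, c = wk$c,
            ang = wk$ang + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.0),
            radius = max(1L, wk$radius - 1L),
            life = round(wk$life / 2))
        }
      }
    }
  })
  out <- matrix(as.integer(mask), height, width)
  attr(out, "vessel_fraction") <- mean(mask)
  out
}

#' Simulate a degraded probability map from a ground-truth mask
#'
#' Emulates the output of a segmentation network of tunable quality: the
#' mask is smoothed with a Gaussian blur of width `sigma` (soft vessel
#' edges) and mixed with a seeded uniform noise field scaled by
#' `(1 - quality)`. `quality = 1` with `sigma = 0` and `noise = 0`
#' reproduces the mask exactly; `quality = 0` with full-amplitude noise
#' yields a map carrying no information about the mask.
#'
#' @param mask Binary 0/1 matrix (ground truth).
#' @param quality Degradation control in \[0, 1\]; weight of the signal in
#'   the signal/noise mixture.
#' @param sigma Gaussian blur width in pixels (0 = no blur).
#' @param noise Noise amplitude in \[0, 1\]: 0 pins the noise field at 0.5,
#'   1 spreads it over the full \[0, 1\] range.
#' @param seed Integer seed for the noise field.
#' @return Numeric matrix in \[0, 1\].
#' @export
simulate_probability_map <- function(mask, quality = 0.8, sigma = 1.5,
                                     noise = 1, seed = NULL) {
  mask <- as_binary_mask(mask)
  if (quality < 0 || quality > 1) stop("quality must be in [0, 1]", call. = FALSE)
  base <- matrix(as.double(mask), nrow(mask), ncol(mask))
  if (sigma > 0) {
    base <- EBImage::gblur(base, sigma = sigma)
    base <- pmin(pmax(base, 0), 1)
  }
  eta <- with_seed(seed,
                   0.5 + noise * (stats::runif(length(base)) - 0.5))
  out <- quality * base + (1 - quality) * matrix(eta, nrow(base), ncol(base))
  pmin(pmax(out, 0), 1)
}

#' Simulate stage-2 pairwise-comparison responses
#'
#' Every observer answers every survey. Non-control choices are drawn from
#' the latent quality model's preference probabilities; a control question
#' repeats the observer's original answer with probability equal to their
#' `consistency`, and is redrawn from the preference model otherwise.
#'
#' @param qm A [latent_quality_model()] covering every compared model.
#' @param observers Data frame from [simulated_observers()].
#' @param surveys List of `survey` objects (stage 2).
#' @param seed Integer seed; responses are deterministic given it.
#' @return Stage-2 response data frame (`observer_id`, `question_id`,
#'   `image_id`, `dataset`, `model_a`, `model_b`, `chosen`, `is_control`,
#'   `source_question_id`).
#' @export
simulate_pairwise_responses <- function(qm, observers, surveys, seed = NULL) {
  qs <- do.call(rbind, lapply(surveys, `[[`, "questions"))
  unknown <- setdiff(unique(c(qs$model_a, qs$model_b)), qm$models)
  if (length(unknown))
    stop("models without latent quality: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  with_seed(seed, {
    out <- lapply(observers$observer_id, function(o) {
      cons <- observers$consistency[observers$observer_id == o]
      r <- qs
      r$observer_id <- o
      p_a <- stats::plogis(qm$beta * (qm$qualities[r$model_a] -
                                        qm$qualities[r$model_b]))
      r$chosen <- ifelse(stats::runif(nrow(r)) < p_a, r$model_a, r$model_b)
      # controls: repeat the original answer with probability `consistency`
      is_c <- r$is_control
      if (any(is_c)) {
        orig <- match(r$source_question_id[is_c], r$question_id)
        keep <- stats::runif(sum(is_c)) < cons
        r$chosen[is_c][keep] <- r$chosen[orig][keep]
      }
      r
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[, c("observer_id", "question_id", "image_id", "dataset", "model_a",
            "model_b", "chosen", "is_control", "source_question_id")]
  })
}

#' Simulate stage-1 diagnosis responses
#'
#' Each observer answers each diagnosis question: with probability equal to
#' their per-category accuracy they select a (uniformly chosen) member of
#' the image's truth set; otherwise they answer "not applicable" with
#' probability `na_prob` or a uniformly chosen wrong category. Certainty is
#' drawn from a correctness-conditional Likert distribution. Controls
#' repeat the original answer (and certainty) with probability
#' `consistency`.
#'
#' @param observers Data frame from [simulated_observers()].
#' @param surveys List of stage-1 `survey` objects.
#' @param labels Label table as from [study_image_labels()].
#' @param certainty_correct,certainty_incorrect Probability vectors over
#'   Likert levels 1..5, conditional on a correct / not-correct answer.
#' @param seed Integer seed.
#' @return Stage-1 response data frame.
#' @export
simulate_stage1_responses <- function(observers, surveys,
                                      labels = study_image_labels(),
                                      certainty_correct = c(0.05, 0.10, 0.20, 0.30, 0.35),
                                      certainty_incorrect = c(0.10, 0.20, 0.30, 0.25, 0.15),
                                      seed = NULL) {
  qs <- do.call(rbind, lapply(surveys, `[[`, "questions"))
  truth_of <- stats::setNames(labels$truth, labels$image_id)
  if (!all(qs$image_id %in% names(truth_of)))
    stop("questions reference images without ground truth", call. = FALSE)
  cats <- diagnosis_categories()
  with_seed(seed, {
    out <- lapply(seq_len(nrow(observers)), function(oi) {
      acc <- observers$accuracy[oi]
      nap <- observers$na_prob[oi]
      cons <- observers$consistency[oi]
      r <- qs
      r$observer_id <- observers$observer_id[oi]
      ans <- vapply(r$image_id, function(img) {
        truth <- truth_of[[img]]
        if (stats::runif(1) < acc) {
          sample(rep(truth, 2L), 1L)  # rep() guards length-1 sample()
        } else if (stats::runif(1) < nap) {
          NOT_APPLICABLE
        } else {
          wrong <- setdiff(cats, truth)
          sample(rep(wrong, 2L), 1L)
        }
      }, character(1))
      r$selected <- ans
      correct <- vapply(seq_len(nrow(r)), function(i)
        r$selected[i] %in% truth_of[[r$image_id[i]]], logical(1))
      r$certainty <- ifelse(
        r$selected == NOT_APPLICABLE, NA_integer_,
        ifelse(correct,
               sample(1:5, nrow(r), TRUE, certainty_correct),
               sample(1:5, nrow(r), TRUE, certainty_incorrect)))
      is_c <- r$is_control
      if (any(is_c)) {
        orig <- match(r$source_question_id[is_c], r$question_id)
        keep <- stats::runif(sum(is_c)) < cons
        r$selected[is_c][keep] <- r$selected[orig][keep]
        r$certainty[is_c][keep] <- r$certainty[orig][keep]
      }
      r
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[, c("observer_id", "question_id", "image_id", "dataset", "model",
            "selected", "certainty", "is_control", "source_question_id")]
  })
}

#' Simulate a complete stage-2 ranking study
#'
#' Convenience wrapper reproducing the structure of the ranking experiment
#' at a configurable scale: one 42-question pairwise survey (28 pairs of 8
#' models plus one-third controls by default) per image, answered by every
#' observer under a latent quality model.
#'
#' @param qm A [latent_quality_model()].
#' @param n_images Named vector of image counts per dataset, e.g.
#'   `c(DRIVE = 40, STARE = 20, CHASE = 28)`.
#' @param observers Data frame from [simulated_observers()].
#' @param control_fraction Control share per survey; default one third.
#' @param seed Master seed; survey construction and responses draw from
#'   derived substreams so each part is independently reproducible.
#' @return List with `surveys` (list of `survey`) and `responses`
#'   (stage-2 response data frame).
#' @export
simulate_stage2_study <- function(qm,
                                  n_images = c(DRIVE = 40, STARE = 20, CHASE = 28),
                                  observers = simulated_observers(4),
                                  control_fraction = 1 / 3,
                                  seed = 1L) {
  manifest <- build_manifest(n_images, qm$models)
  images <- unique(manifest[, c("image_id", "dataset")])
  surveys <- lapply(seq_len(nrow(images)), function(i) {
    qs <- generate_pairwise_questions(qm$models, images$image_id[i],
                                      images$dataset[i],
                                      seed = seed + 13L * i)
    inject_controls(qs, control_fraction, seed = seed + 13L * i + 7L,
                    survey_id = paste0("stage2_", images$image_id[i]))
  })
  responses <- simulate_pairwise_responses(qm, observers, surveys,
                                           seed = seed + 104729L)
  list(surveys = surveys, responses = responses)
}
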