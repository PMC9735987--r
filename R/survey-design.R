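#' @importFrom stats runif rnorm quantile var cor sd pt qt qf pnorm qnorm
#'   rbinom fivenum
#' @importFrom utils combn read.csv write.csv
NULL

#' Sentinel answer for images judged unusable for diagnosis
#' @export
NOT_APPLICABLE <- "Not applicable for diagnosis"

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls do not perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Round-half-up (2.5 -> 3), unlike base round()'s round-half-even.
round_half_up <- function(x) floor(x + 0.5)

#' Canonical diagnostic categories used in stage-1 surveys
#'
#' Central retinal artery occlusion and central retinal vein occlusion are
#' merged into a single artery/vein occlusion category because binary vessel
#' masks cannot distinguish arteries from veins, and background diabetic
#' retinopathy is folded into diabetic retinopathy for uniform nomenclature
#' across source datasets.
#'
#' @return Character vector of category names (excluding the
#'   "not applicable" option, see [NOT_APPLICABLE]).
#' @export
diagnosis_categories <- function() {
  c("Diabetic retinopathy",
    "Arteriosclerotic retinopathy",
    "Cilio-retinal artery occlusion",
    "Central artery/vein occlusion")
}

# Source-dataset diagnosis string -> canonical category (or categories, for
# images annotated with alternative diagnoses).
diagnosis_label_map <- function() {
  list(
    "background diabetic retinopathy" = "Diabetic retinopathy",
    "diabetic retinopathy" = "Diabetic retinopathy",
    "arteriosclerotic retinopathy" = "Arteriosclerotic retinopathy",
    "arteriosclerotic retinopathy and choroidal neovascularization" =
      "Arteriosclerotic retinopathy",
    "cilio-retinal artery occlusion" = "Cilio-retinal artery occlusion",
    "cilio-retinal artery occlusion or arteriosclerotic retinopathy" =
      c("Cilio-retinal artery occlusion", "Arteriosclerotic retinopathy"),
    "central retinal artery occlusion and central retinal vein occlusion" =
      "Central artery/vein occlusion",
    "central artery/vein occlusion" = "Central artery/vein occlusion"
  )
}

#' Map a source-dataset diagnosis string to canonical categories
#'
#' @param raw_label Diagnosis string as given by the source dataset's
#'   authors (case-insensitive).
#' @return Character vector of one or more canonical categories; images
#'   annotated with alternative diagnoses ("A or B") map to both, and a
#'   selection of either counts as correct.
#' @examples
#' map_diagnosis("Background diabetic retinopathy")
#' @export
map_diagnosis <- function(raw_label) {
  if (!is.character(raw_label) || length(raw_label) != 1L || !nzchar(raw_label))
    stop("unknown diagnosis label: ", deparse(raw_label), call. = FALSE)
  key <- tolower(trimws(raw_label))
  m <- diagnosis_label_map()
  if (!key %in% names(m))
    stop("unknown diagnosis label: ", raw_label, call. = FALSE)
  m[[key]]
}

#' Ground-truth diagnoses of the pathological study images
#'
#' The 12 fundus images (7 DRIVE, 5 STARE) with known pathology that anchor
#' the stage-1 diagnosis surveys, with their source annotations and the
#' canonical truth set for scoring.
#'
#' @return Data frame with columns `image_id`, `dataset`, `raw_diagnosis`
#'   and a list column `truth` of canonical category sets.
#' @export
study_image_labels <- function() {
  path <- system.file("extdata", "stage1_labels.csv", package = "vesselrank")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$truth <- lapply(df$raw_diagnosis, map_diagnosis)
  df
}

#' Score a selected diagnosis against the ground-truth set
#'
#' @param selected Canonical category chosen by the observer, or
#'   [NOT_APPLICABLE] when the mask was judged unusable.
#' @param truth_set Non-empty character vector of canonical categories that
#'   count as correct for the image.
#' @return 1 (correct), -1 (incorrect) or 0 (not applicable).
#' @export
is_correct <- function(selected, truth_set) {
  if (length(truth_set) == 0L) stop("empty truth set", call. = FALSE)
  if (identical(selected, NOT_APPLICABLE)) return(0L)
  if (selected %in% truth_set) 1L else -1L
}

#' Build an evaluation-dataset manifest
#'
#' Enumerates every (image, model) combination: each fundus image in each
#' dataset contributes one segmentation mask per model. The study
#' configuration of 40 + 20 + 28 images and 8 models yields 704 masks.
#'
#' @param dataset_sizes Named integer vector of image counts per dataset,
#'   e.g. `c(DRIVE = 40, STARE = 20, CHASE = 28)`.
#' @param models Character vector of distinct model tags.
#' @return Data frame with columns `image_id`, `dataset`, `model`,
#'   `mask_ref`; `(image_id, model)` pairs are unique.
#' @export
build_manifest <- function(dataset_sizes, models) {
  if (is.null(names(dataset_sizes)) || any(!nzchar(names(dataset_sizes))))
    stop("`dataset_sizes` must be a named vector", call. = FALSE)
  if (any(dataset_sizes < 0)) stop("image counts must be >= 0", call. = FALSE)
  if (anyDuplicated(models)) stop("duplicate model tags", call. = FALSE)
  images <- do.call(rbind, lapply(names(dataset_sizes), function(d) {
    n <- dataset_sizes[[d]]
    if (n == 0) return(NULL)
    data.frame(image_id = sprintf("%s_%03d", d, seq_len(n)), dataset = d,
               stringsAsFactors = FALSE)
  }))
  if (is.null(images))
    return(data.frame(image_id = character(), dataset = character(),
                      model = character(), mask_ref = character(),
                      stringsAsFactors = FALSE))
  out <- merge(images, data.frame(model = models, stringsAsFactors = FALSE))
  out <- out[order(out$dataset, out$image_id, out$model), ]
  out$mask_ref <- file.path(out$dataset, out$model,
                            paste0(out$image_id, ".png"))
  rownames(out) <- NULL
  out[, c("image_id", "dataset", "model", "mask_ref")]
}

#' Generate pairwise-comparison questions for one reference image
#'
#' One question per unordered model pair (combinations without repetition),
#' so `m` models yield `choose(m, 2)` questions. Which mask appears on the
#' left is randomized per question to suppress position bias.
#'
#' @param models Character vector of `m >= 2` distinct model tags.
#' @param image_id,dataset Identify the reference fundus image.
#' @param seed Integer seed controlling left/right placement.
#' @return Data frame of questions: `question_id`, `image_id`, `dataset`,
#'   `model_a`, `model_b`, `left_model`, `is_control`,
#'   `source_question_id`.
#' @export
generate_pairwise_questions <- function(models, image_id, dataset = NA_character_,
                                        seed = NULL) {
  if (length(models) < 2L) stop("need at least 2 models", call. = FALSE)
  if (anyDuplicated(models)) stop("duplicate model tags", call. = FALSE)
  pairs <- utils::combn(models, 2L)
  k <- ncol(pairs)
  left_is_a <- with_seed(seed, stats::runif(k) < 0.5)
  data.frame(
    question_id = sprintf("%s_q%02d", image_id, seq_len(k)),
    image_id = image_id, dataset = dataset,
    model_a = pairs[1L, ], model_b = pairs[2L, ],
    left_model = ifelse(left_is_a, pairs[1L, ], pairs[2L, ]),
    is_control = FALSE, source_question_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Inject intra-observer control questions into a survey
#'
#' Controls are verbatim copies of base questions (same image and model
#' pair, independently re-randomized left/right placement), sampled without
#' replacement and appended after the base block so each control follows its
#' original. The control count is chosen so controls make up
#' `control_fraction` of the final survey: `round(n_base * f / (1 - f))`,
#' rounding half up. A 28-question pairwise block with a one-third fraction
#' therefore gains 14 controls for a 42-question survey.
#'
#' @param questions Data frame of base questions as produced by
#'   [generate_pairwise_questions()] or the stage-1 builder.
#' @param control_fraction Target fraction of controls in the final survey,
#'   in `[0, 1)`.
#' @param seed Integer seed for control sampling, ordering and placement.
#' @param survey_id Identifier stored on the survey object.
#' @param stage Survey stage, 1 or 2.
#' @return A `survey` object: list with `survey_id`, `stage`, `seed` and the
#'   `questions` data frame.
#' @export
inject_controls <- function(questions, control_fraction = 1 / 3, seed = NULL,
                            survey_id = "survey", stage = 2L) {
  if (control_fraction < 0 || control_fraction >= 1)
    stop("`control_fraction` must be in [0, 1)", call. = FALSE)
  n_base <- nrow(questions)
  n_ctrl <- round_half_up(n_base * control_fraction / (1 - control_fraction))
  if (n_ctrl > n_base)
    stop("requested controls exceed the number of base questions",
         call. = FALSE)
  qs <- questions
  if (n_ctrl > 0) {
    ctrl <- with_seed(seed, {
      idx <- sample.int(n_base, n_ctrl)
      flip <- stats::runif(n_ctrl) < 0.5
      list(idx = idx, flip = flip)
    })
    dup <- questions[ctrl$idx, , drop = FALSE]
    dup$source_question_id <- dup$question_id
    dup$question_id <- paste0(dup$question_id, "_ctrl")
    dup$is_control <- TRUE
    if ("left_model" %in% names(dup)) {
      dup$left_model <- ifelse(ctrl$flip, dup$model_a, dup$model_b)
    }
    qs <- rbind(questions, dup)
  }
  rownames(qs) <- NULL
  structure(list(survey_id = survey_id, stage = as.integer(stage),
                 seed = seed, questions = qs),
            class = "survey")
}

#' @export
print.survey <- function(x, ...) {
  cat("<survey>", x$survey_id, "stage", x$stage, "-",
      nrow(x$questions), "questions (",
      sum(x$questions$is_control), "controls )\n")
  invisible(x)
}

#' Build the stage-1 diagnosis survey series
#'
#' Composes `n_regular` surveys of `questions_per_survey` diagnosis
#' questions each by seed-driven uniform sampling of (image, model) items,
#' followed by `n_control_surveys` surveys made up entirely of questions
#' resampled without replacement from the regular ones and flagged as
#' controls. The defaults mirror a series of eight 15-question surveys with
#' the last two serving as intra-observer consistency probes. A model
#' exclusion list allows reproducing runs in which one model's masks were
#' left out of survey composition.
#'
#' @param items Manifest data frame (`image_id`, `dataset`, `model`) of
#'   candidate masks; typically built over pathological images only.
#' @param questions_per_survey Questions per survey (default 15).
#' @param n_regular Number of regular surveys (default 6).
#' @param n_control_surveys Number of all-control surveys (default 2).
#' @param seed Integer seed driving all sampling.
#' @param exclude_models Optional model tags removed from `items` first.
#' @return List of `survey` objects, regular surveys first.
#' @export
build_stage1_surveys <- function(items, questions_per_survey = 15L,
                                 n_regular = 6L, n_control_surveys = 2L,
                                 seed = NULL, exclude_models = character()) {
  items <- items[!(items$model %in% exclude_models), , drop = FALSE]
  n_needed <- n_regular * questions_per_survey
  if (nrow(items) == 0L) stop("no items to sample from", call. = FALSE)
  n_ctrl_q <- n_control_surveys * questions_per_survey
  if (n_ctrl_q > n_needed)
    stop("more control questions requested than regular questions exist",
         call. = FALSE)
  with_seed(seed, {
    # sample items without replacement while the pool lasts, then reuse
    reps <- ceiling(n_needed / nrow(items))
    pool <- unlist(lapply(seq_len(reps), function(i) sample.int(nrow(items))))
    idx <- pool[seq_len(n_needed)]
    regular <- lapply(seq_len(n_regular), function(s) {
      rows <- items[idx[((s - 1) * questions_per_survey + 1):
                          (s * questions_per_survey)], , drop = FALSE]
      qs <- data.frame(
        question_id = sprintf("s1_%02d_q%02d", s, seq_len(nrow(rows))),
        image_id = rows$image_id, dataset = rows$dataset, model = rows$model,
        is_control = FALSE, source_question_id = NA_character_,
        stringsAsFactors = FALSE)
      structure(list(survey_id = sprintf("stage1_%02d", s), stage = 1L,
                     seed = seed, questions = qs), class = "survey")
    })
    all_regular <- do.call(rbind, lapply(regular, `[[`, "questions"))
    ctrl_idx <- sample.int(nrow(all_regular), n_ctrl_q)
    control <- lapply(seq_len(n_control_surveys), function(s) {
      take <- ctrl_idx[((s - 1) * questions_per_survey + 1):
                         (s * questions_per_survey)]
      src <- all_regular[take, , drop = FALSE]
      qs <- src
      qs$source_question_id <- src$question_id
      qs$question_id <- sprintf("s1_c%02d_q%02d", s, seq_len(nrow(src)))
      qs$is_control <- TRUE
      rownames(qs) <- NULL
      structure(list(survey_id = sprintf("stage1_ctrl_%02d", s), stage = 1L,
                     seed = seed, questions = qs), class = "survey")
    })
    c(regular, control)
  })
}

#' Serialize a survey to JSON
#'
#' Keys appear in a stable order so surveys regenerated with the same seed
#' are byte-identical on disk.
#'
#' @param survey A `survey` object.
#' @param path Output file path.
#' @export
write_survey_json <- function(survey, path) {
  obj <- list(survey_id = survey$survey_id, stage = survey$stage,
              seed = survey$seed, questions = survey$questions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a survey back from JSON
#' @param path File written by [write_survey_json()].
#' @return A `survey` object.
#' @export
read_survey_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qs <- as.data.frame(obj$questions, stringsAsFactors = FALSE)
  if (!"source_question_id" %in% names(qs)) qs$source_question_id <- NA_character_
  qs$source_question_id <- as.character(qs$source_question_id)
  structure(list(survey_id = obj$survey_id, stage = as.integer(obj$stage),
                 seed = obj$seed, questions = qs), class = "survey")
}
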