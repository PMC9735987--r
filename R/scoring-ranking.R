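#' Grading score for one diagnosis response
#'
#' The grade is `is_correct * certainty`: positive for a correct diagnosis
#' (up to +5 at full certainty), negative for an incorrect one (down to -5),
#' and 0 when the observer marked the mask as not applicable for diagnosis,
#' regardless of certainty.
#'
#' @param selected Canonical category chosen, or [NOT_APPLICABLE].
#' @param certainty Likert certainty in 1..5 (uncertain to completely
#'   certain); may be `NA` only for not-applicable answers.
#' @param truth_set Character vector of correct categories for the image.
#' @return Integer grade in -5..5.
#' @examples
#' compute_grade("Diabetic retinopathy", 5, "Diabetic retinopathy")  # +5
#' compute_grade("Diabetic retinopathy", 5, "Central artery/vein occlusion")
#' @export
compute_grade <- function(selected, certainty, truth_set) {
  ic <- is_correct(selected, truth_set)
  if (ic == 0L) return(0L)
  if (is.na(certainty) || !certainty %in% 1:5)
    stop("certainty must be in 1..5 for a diagnosis answer", call. = FALSE)
  ic * as.integer(certainty)
}

#' Grade a table of stage-1 diagnosis responses
#'
#' Joins each response to its image's ground-truth set and applies the
#' grading formula. Rows with a missing or out-of-range certainty on a
#' substantive answer are flagged and excluded with a warning, as are
#' responses to images absent from the label table.
#'
#' @param responses Data frame with columns `observer_id`, `question_id`,
#'   `image_id`, `dataset`, `model`, `selected`, `certainty`, `is_control`
#'   (and optionally `source_question_id`).
#' @param labels Label table as from [study_image_labels()]: `image_id` plus
#'   a list column `truth`.
#' @return The responses with added integer columns `is_correct` and
#'   `grade`, invalid rows removed.
#' @export
grade_responses <- function(responses, labels = study_image_labels()) {
  truth_of <- stats::setNames(labels$truth, labels$image_id)
  known <- responses$image_id %in% names(truth_of)
  na_ans <- responses$selected == NOT_APPLICABLE
  bad_cert <- !na_ans & (is.na(responses$certainty) |
                           !responses$certainty %in% 1:5)
  drop <- !known | bad_cert
  if (any(drop))
    warning(sum(drop), " response(s) dropped (unknown image or invalid certainty)",
            call. = FALSE)
  out <- responses[!drop, , drop = FALSE]
  out$is_correct <- vapply(seq_len(nrow(out)), function(i)
    is_correct(out$selected[i], truth_of[[out$image_id[i]]]), integer(1))
  out$grade <- ifelse(out$is_correct == 0L, 0L,
                      out$is_correct * as.integer(out$certainty))
  rownames(out) <- NULL
  out
}

#' Tally head-to-head wins from pairwise-comparison responses
#'
#' @param responses Data frame of stage-2 responses: `observer_id`,
#'   `question_id`, `image_id`, `dataset`, `model_a`, `model_b`, `chosen`,
#'   `is_control` (and optionally `source_question_id`).
#' @param models Optional model tags fixing the tally's row/column order;
#'   defaults to the sorted union of models seen in `responses`.
#' @param include_controls Count control responses too? Controls duplicate
#'   information and are excluded from ranking tallies by default.
#' @return A `head_to_head` object: square integer matrix `w` with
#'   `w[i, j]` = number of responses preferring model i over model j.
#' @export
tally_head_to_head <- function(responses, models = NULL,
                               include_controls = FALSE) {
  r <- responses
  if (!include_controls && "is_control" %in% names(r))
    r <- r[!r$is_control, , drop = FALSE]
  if (is.null(models))
    models <- sort(unique(c(r$model_a, r$model_b)))
  w <- matrix(0L, length(models), length(models),
              dimnames = list(winner = models, loser = models))
  if (nrow(r)) {
    bad <- !(r$chosen == r$model_a | r$chosen == r$model_b)
    if (any(bad))
      stop("`chosen` must be one of the two compared models", call. = FALSE)
    loser <- ifelse(r$chosen == r$model_a, r$model_b, r$model_a)
    tab <- table(factor(r$chosen, models), factor(loser, models))
    w[] <- w + as.integer(tab)
  }
  structure(list(w = w, models = models), class = "head_to_head")
}

#' Copeland ranking from a head-to-head tally
#'
#' Uses the +1/0/-1 strategy: for each unordered model pair, the model
#' winning the majority of their head-to-head comparisons gains +1 and the
#' other -1; ties (including pairs never compared) score 0 for both. A
#' model's Copeland score is the sum over its m - 1 opponents, so scores lie
#' in `[-(m-1), m-1]` and sum to zero; a positive score means the model won
#' more pairwise majorities than it lost.
#'
#' @param tally A `head_to_head` object from [tally_head_to_head()].
#' @return A `copeland_table` data frame: `model`, `score`, `wins`,
#'   `losses`, `ties`, ordered by decreasing score (ties broken
#'   lexicographically by model tag).
#' @export
copeland <- function(tally) {
  w <- tally$w
  m <- length(tally$models)
  if (m < 2L) stop("need at least 2 models to rank", call. = FALSE)
  wins <- losses <- ties <- integer(m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (w[i, j] > w[j, i]) {
        wins[i] <- wins[i] + 1L; losses[j] <- losses[j] + 1L
      } else if (w[i, j] < w[j, i]) {
        wins[j] <- wins[j] + 1L; losses[i] <- losses[i] + 1L
      } else {
        ties[i] <- ties[i] + 1L; ties[j] <- ties[j] + 1L
      }
    }
  }
  out <- data.frame(model = tally$models, score = wins - losses,
                    wins = wins, losses = losses, ties = ties,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$model), ]
  rownames(out) <- NULL
  class(out) <- c("copeland_table", "data.frame")
  out
}

#' Copeland ranking factored by dataset or observer
#'
#' Splits the responses by a factor and ranks within each level, so e.g.
#' per-dataset tables reveal dataset-specific biases the overall ranking
#' hides.
#'
#' @param responses Stage-2 response data frame.
#' @param factor One of `"dataset"` or `"observer"`.
#' @param models Optional fixed model ordering for all levels.
#' @param include_controls Passed to [tally_head_to_head()].
#' @return Named list of `copeland_table`s, one per factor level.
#' @export
factored_copeland <- function(responses, factor = c("dataset", "observer"),
                              models = NULL, include_controls = FALSE) {
  factor <- match.arg(factor)
  col <- if (factor == "dataset") "dataset" else "observer_id"
  if (is.null(models))
    models <- sort(unique(c(responses$model_a, responses$model_b)))
  levels <- sort(unique(responses[[col]]))
  out <- lapply(levels, function(l) {
    copeland(tally_head_to_head(responses[responses[[col]] == l, , drop = FALSE],
                                models = models,
                                include_controls = include_controls))
  })
  stats::setNames(out, levels)
}

#' Condorcet winner of a head-to-head tally
#'
#' @param tally A `head_to_head` object.
#' @return The tag of the model that wins every head-to-head majority
#'   outright, or `NA_character_` when no strict winner exists (ties and
#'   preference cycles both prevent one).
#' @export
condorcet_winner <- function(tally) {
  w <- tally$w
  for (i in seq_along(tally$models)) {
    others <- setdiff(seq_along(tally$models), i)
    if (all(w[i, others] > w[others, i])) return(tally$models[i])
  }
  NA_character_
}

#' Per-class diagnostic accuracy of stage-1 responses
#'
#' For each canonical category: the share of correct answers among
#' responses to images whose truth set includes the category. On images
#' carrying alternative diagnoses a correct answer is credited to the
#' category the observer actually selected. Prevalence is reported under
#' both conventions — share of survey questions and share of distinct study
#' images whose truth includes the category. Categories without responses
#' are reported as `NA`, not 0.
#'
#' @param graded Responses with `is_correct` as from [grade_responses()].
#' @param labels Label table as from [study_image_labels()].
#' @return Data frame: `category`, `n_responses`, `n_correct`,
#'   `accuracy` (percent), `prevalence_questions` and `prevalence_images`
#'   (percent).
#' @export
per_class_accuracy <- function(graded, labels = study_image_labels()) {
  truth_of <- stats::setNames(labels$truth, labels$image_id)
  cats <- diagnosis_categories()
  resp_truth <- truth_of[graded$image_id]
  rows <- lapply(cats, function(cat) {
    in_cat <- vapply(resp_truth, function(ts) cat %in% ts, logical(1))
    n <- sum(in_cat)
    n_correct <- sum(in_cat & graded$is_correct == 1L &
                       graded$selected == cat)
    img_in_cat <- vapply(labels$truth, function(ts) cat %in% ts, logical(1))
    data.frame(category = cat, n_responses = n, n_correct = n_correct,
               accuracy = if (n > 0) 100 * n_correct / n else NA_real_,
               prevalence_questions = if (nrow(graded) > 0)
                 100 * n / nrow(graded) else NA_real_,
               prevalence_images = 100 * sum(img_in_cat) / nrow(labels),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grade distribution summaries by grouping
#'
#' Histograms over the -5..5 grade range plus five-number summaries, grouped
#' by observer, dataset, or their crossings with dataset/model — the grouped
#' views used to compare observers and networks.
#'
#' @param graded Graded responses (column `grade`).
#' @param group_by One of `"observer"`, `"dataset"`,
#'   `"observer_dataset"`, `"observer_model"`.
#' @return List with `counts` (long data frame: group columns, `grade`,
#'   `count`) and `summary` (group columns, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`).
#' @export
grade_summaries <- function(graded,
                            group_by = c("observer", "dataset",
                                         "observer_dataset",
                                         "observer_model")) {
  group_by <- match.arg(group_by)
  cols <- switch(group_by,
                 observer = "observer_id",
                 dataset = "dataset",
                 observer_dataset = c("observer_id", "dataset"),
                 observer_model = c("observer_id", "model"))
  key <- interaction(graded[cols], drop = TRUE, lex.order = TRUE, sep = "\r")
  grades <- -5:5
  counts <- do.call(rbind, lapply(levels(key), function(k) {
    g <- graded$grade[key == k]
    id <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cbind(as.data.frame(as.list(stats::setNames(id, cols)),
                        stringsAsFactors = FALSE),
          data.frame(grade = grades,
                     count = as.integer(table(factor(g, levels = grades)))))
  }))
  summary <- do.call(rbind, lapply(levels(key), function(k) {
    g <- graded$grade[key == k]
    fn <- stats::fivenum(g)
    id <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cbind(as.data.frame(as.list(stats::setNames(id, cols)),
                        stringsAsFactors = FALSE),
          data.frame(min = fn[1], q1 = fn[2], median = fn[3], q3 = fn[4],
                     max = fn[5], n = length(g)))
  }))
  rownames(counts) <- rownames(summary) <- NULL
  list(counts = counts, summary = summary)
}

#' Pair subjective Copeland scores with objective metric values
#'
#' Aligns a Copeland table with per-model objective metric values (accuracy,
#' F1, ...) for scatter plotting, optionally computing a rank-correlation
#' coefficient. With very few models a coefficient is nearly meaningless,
#' so it is only computed on request and always reported with its n.
#'
#' @param copeland_table A `copeland_table`.
#' @param objective Data frame with columns `model` and `value` (one metric).
#' @param coefficient `"none"` (default), `"spearman"` or `"kendall"`.
#' @return List with `pairs` (model, score, value), `n`, and — when a
#'   coefficient is requested — `coefficient` and `estimate`.
#' @export
rank_vs_objective <- function(copeland_table, objective,
                              coefficient = c("none", "spearman", "kendall")) {
  coefficient <- match.arg(coefficient)
  merged <- merge(copeland_table[, c("model", "score")],
                  objective[, c("model", "value")], by = "model")
  if (nrow(merged) < 2L)
    stop("model sets share fewer than 2 models", call. = FALSE)
  merged <- merged[order(merged$model), ]
  rownames(merged) <- NULL
  out <- list(pairs = merged, n = nrow(merged))
  if (coefficient != "none") {
    out$coefficient <- coefficient
    out$estimate <- stats::cor(merged$score, merged$value,
                               method = coefficient)
  }
  out
}

#' Read stage-1 (diagnosis) responses from CSV
#'
#' Expected header: `observer_id,question_id,image_id,dataset,model,
#' selected,certainty,is_control,source_question_id`.
#'
#' @param path CSV file path.
#' @return Data frame with typed columns.
#' @export
read_stage1_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "question_id", "image_id", "dataset", "model",
            "selected", "certainty", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$is_control <- as.logical(df$is_control)
  df$certainty <- suppressWarnings(as.integer(df$certainty))
  if (!"source_question_id" %in% names(df))
    df$source_question_id <- NA_character_
  df
}

#' Read stage-2 (pairwise) responses from CSV
#'
#' Expected header: `observer_id,question_id,image_id,dataset,model_a,
#' model_b,chosen,is_control,source_question_id`.
#'
#' @param path CSV file path.
#' @return Data frame with typed columns.
#' @export
read_stage2_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "question_id", "image_id", "dataset", "model_a",
            "model_b", "chosen", "is_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$is_control <- as.logical(df$is_control)
  if (!"source_question_id" %in% names(df))
    df$source_question_id <- NA_character_
  df
}
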