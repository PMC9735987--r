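# Shared fixture builders: everything is generated in code at test time.

study_models <- function(m = 8) paste0("net", LETTERS[seq_len(m)])

# Stage-1 item manifest over the pathological study images.
stage1_items <- function(models = study_models(7)) {
  labs <- study_image_labels()
  do.call(rbind, lapply(models, function(mo)
    data.frame(image_id = labs$image_id, dataset = labs$dataset, model = mo,
               stringsAsFactors = FALSE)))
}

# A small hand-built head-to-head tally from explicit win counts.
tally_from_counts <- function(models, wins) {
  w <- matrix(0L, length(models), length(models),
              dimnames = list(winner = models, loser = models))
  for (k in seq_len(nrow(wins)))
    w[wins$i[k], wins$j[k]] <- as.integer(wins$n[k])
  structure(list(w = w, models = models), class = "head_to_head")
}

# Independent Copeland oracle: per-pair majority enumeration on the matrix.
copeland_oracle <- function(w) {
  m <- nrow(w)
  score <- integer(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    if (w[i, j] > w[j, i]) score[i] <- score[i] + 1L
    if (w[i, j] < w[j, i]) score[i] <- score[i] - 1L
  }
  stats::setNames(score, rownames(w))
}

# Random head-to-head tally over m models with counts in 0..max_count.
random_tally <- function(m, max_count = 10) {
  models <- study_models(m)
  w <- matrix(sample(0:max_count, m * m, replace = TRUE), m, m,
              dimnames = list(winner = models, loser = models))
  diag(w) <- 0L
  storage.mode(w) <- "integer"
  structure(list(w = w, models = models), class = "head_to_head")
}
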