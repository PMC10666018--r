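# Template files: a CSV holding the normalized-time reference trajectories
# plus a JSON sidecar for the scoring metadata (triples, weights, threshold,
# repetition duration).

#' Write a gesture template to disk
#'
#' @param template A [gesture_template()].
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_gesture_template <- function(template, path) {
  df <- data.frame(time = seq(0, 1, length.out = nrow(template$ref)),
                   template$ref, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(exercise_id = template$exercise_id,
               columns = colnames(template$ref),
               triples = template$triples,
               weights = template$weights,
               threshold = template$threshold,
               duration_s = template$duration_s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a gesture template from disk
#'
#' @param path CSV path written by [write_gesture_template()].
#' @return A [gesture_template()].
#' @export
read_gesture_template <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ref <- as.matrix(df[, meta$columns, drop = FALSE])
  triples <- meta$triples
  if (is.matrix(triples)) triples <- split(triples, row(triples))
  if (!is.list(triples)) triples <- list(triples)
  triples <- unname(lapply(triples, function(tr) as.character(unlist(tr))))
  gesture_template(meta$exercise_id, ref, triples,
                   weights = meta$weights, threshold = meta$threshold,
                   duration_s = meta$duration_s)
}
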