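#' Built-in Pilates exercise catalog
#'
#' The default catalog encodes the exercises named in the training program —
#' breathing (mermaids, arm circles), posture (arch-and-curl, spine stretch,
#' spine twist, scapola position, elephant) and balance (side-to-side, hip
#' circle, side leg kick, one-leg circle, single leg extension) — with neutral
#' defaults (5 base repetitions, uniform joint weights). Per-exercise joint
#' sets are plausible anatomical choices and fully overridable.
#'
#' @return A `data.frame` with one row per exercise: `id`, `name`,
#'   `category` (breathing/posture/balance), `position`
#'   (sitting/standing/kneeling), `base_reps`, `complexity_level`, and a
#'   list-column `triples` of scored joint triples.
#' @export
default_catalog <- function() {
  mk <- function(id, name, category, position, triples,
                 base_reps = 5L, complexity_level = 1L) {
    list(id = id, name = name, category = category, position = position,
         base_reps = base_reps, complexity_level = complexity_level,
         triples = triples)
  }
  rows <- list(
    mk("side_to_side_1", "Side to side 1", "balance", "standing",
       list("trunk", "hip_left", "hip_right")),
    mk("spine_stretch_1", "Spine Stretch 1", "posture", "sitting",
       list("trunk", "neck")),
    mk("sitting_mermaid_1", "Sitting Mermaid 1", "breathing", "sitting",
       list("trunk", "shoulder_left", "shoulder_right")),
    mk("kneeling_mermaid_1", "Kneeling Mermaid 1", "breathing", "kneeling",
       list("trunk", "shoulder_left", "shoulder_right"),
       complexity_level = 2L),
    mk("one_leg_circle_1", "One leg circle 1", "balance", "standing",
       list("hip_left", "knee_left"), complexity_level = 2L),
    mk("scapola_position_1", "Scapola Position 1", "posture", "standing",
       list("shoulder_left", "shoulder_right")),
    mk("arm_circles_1", "Arm circles 1", "breathing", "sitting",
       list("shoulder_left", "shoulder_right")),
    mk("arch_and_curl_1", "Arch and curl 1", "posture", "sitting",
       list("trunk", "neck")),
    mk("spine_twist_1", "Spine twist 1", "posture", "sitting",
       list("trunk", "shoulder_left", "shoulder_right")),
    mk("elephant_1", "Elephant 1", "posture", "standing",
       list("trunk", "hip_left", "hip_right"), complexity_level = 2L),
    mk("hip_circle_1", "Hip circle 1", "balance", "standing",
       list("hip_left", "hip_right")),
    mk("side_leg_kick_1", "Side leg kick 1", "balance", "standing",
       list("hip_left", "knee_left"), complexity_level = 2L),
    mk("single_leg_extension_1", "Single leg extension 1", "balance",
       "standing", list("knee_left", "hip_left"), complexity_level = 3L)
  )
  catalog_from_rows(rows)
}

CATEGORIES <- c("breathing", "posture", "balance")
POSITIONS <- c("sitting", "standing", "kneeling")

catalog_from_rows <- function(rows) {
  validate_exercise <- function(r) {
    stopifnot(is.character(r$id), nzchar(r$id))
    if (!r$category %in% CATEGORIES)
      stop("unknown category '", r$category, "' for ", r$id)
    if (!r$position %in% POSITIONS)
      stop("unknown position '", r$position, "' for ", r$id)
    if (r$base_reps < 1) stop("base_reps must be >= 1 for ", r$id)
    if (r$complexity_level < 1) stop("complexity_level must be >= 1 for ", r$id)
    r
  }
  rows <- lapply(rows, validate_exercise)
  df <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    name = vapply(rows, `[[`, character(1), "name"),
    category = vapply(rows, `[[`, character(1), "category"),
    position = vapply(rows, `[[`, character(1), "position"),
    base_reps = vapply(rows, function(r) as.integer(r$base_reps), integer(1)),
    complexity_level = vapply(rows, function(r) as.integer(r$complexity_level),
                              integer(1)),
    stringsAsFactors = FALSE
  )
  df$triples <- lapply(rows, `[[`, "triples")
  class(df) <- c("exercise_catalog", "data.frame")
  df
}

#' Load the exercise catalog, with optional overrides
#'
#' Starts from [default_catalog()] and merges a JSON override file: entries
#' whose `id` matches an existing exercise replace the listed fields; new ids
#' are appended. An empty or absent override leaves the default unchanged.
#'
#' @param path Optional JSON file: an array of exercise objects with fields
#'   as in [default_catalog()] (`triples` as arrays of joint names or default
#'   triple names).
#' @return An `exercise_catalog`.
#' @export
load_catalog <- function(path = NULL) {
  cat <- default_catalog()
  if (is.null(path)) return(cat)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(cat)
  entries <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  rows <- split(cat, seq_len(nrow(cat)))
  rows <- lapply(rows, function(r) {
    out <- as.list(r[1, c("id", "name", "category", "position",
                          "base_reps", "complexity_level")])
    out$triples <- r$triples[[1]]
    out
  })
  names(rows) <- cat$id
  for (e in entries) {
    if (is.null(e$id)) stop("catalog override entry lacks an id")
    base <- rows[[e$id]] %||% list(id = e$id, name = e$id,
                                   category = "balance",
                                   position = "standing",
                                   base_reps = 5L, complexity_level = 1L,
                                   triples = list("trunk"))
    for (f in c("name", "category", "position", "base_reps",
                "complexity_level"))
      if (!is.null(e[[f]])) base[[f]] <- e[[f]]
    if (!is.null(e$triples))
      base$triples <- lapply(e$triples, function(tr) unlist(tr))
    rows[[e$id]] <- base
  }
  catalog_from_rows(unname(rows))
}

#' Serialize a catalog to its JSON config form
#'
#' Round-trips through [load_catalog()]'s override format.
#'
#' @param catalog An `exercise_catalog`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  entries <- lapply(seq_len(nrow(catalog)), function(i) {
    list(id = catalog$id[i], name = catalog$name[i],
         category = catalog$category[i], position = catalog$position[i],
         base_reps = catalog$base_reps[i],
         complexity_level = catalog$complexity_level[i],
         triples = catalog$triples[[i]])
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Difficulty-scaled protocol for a city
#'
#' Difficulty grows along the travel itinerary: under the default linear rule
#' every exercise's repetitions increase by `step` per city beyond the first,
#' and exercises above the city's allowed complexity are excluded. Replaying
#' an already-unlocked city reissues that city's protocol unchanged (no
#' further scaling).
#'
#' @param city_index 1-based position in the itinerary (>= 1).
#' @param catalog An `exercise_catalog` (default [default_catalog()]).
#' @param step Repetitions added per city step (default 1).
#' @param complexity_per_city Cities to pass before the next complexity level
#'   opens; allowed level is `1 + (city_index - 1) %/% complexity_per_city`.
#'   Default 2.
#' @param max_city Upper bound of the itinerary (for range checking);
#'   `Inf` disables the check.
#' @return A `data.frame` `(exercise_id, reps)` plus attribute `city_index`.
#' @export
protocol_for_city <- function(city_index, catalog = default_catalog(),
                              step = 1L, complexity_per_city = 2L,
                              max_city = Inf) {
  if (city_index < 1 || city_index != round(city_index))
    stop("city_index must be a positive integer")
  if (city_index > max_city) stop("city_index beyond the itinerary")
  allowed <- 1L + (as.integer(city_index) - 1L) %/% as.integer(complexity_per_city)
  keep <- catalog$complexity_level <= allowed
  out <- data.frame(
    exercise_id = catalog$id[keep],
    reps = catalog$base_reps[keep] + step * (as.integer(city_index) - 1L),
    stringsAsFactors = FALSE
  )
  attr(out, "city_index") <- as.integer(city_index)
  out
}
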