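#' @keywords internal
"_PACKAGE"

# Canonical column sets for the four entity tables.  Missing trait values are
# represented as NA throughout; they are never dropped at ingestion.
.forager_schema <- list(
  individuals = c("individual_id", "sex", "age", "height", "grip", "knowledge"),
  shellfish   = c("individual_id", "trip_id", "returns_kg", "duration_min",
                  "tide_height"),
  traps       = c("trap_id", "installer_id", "trip_id", "exposure_days",
                  "captures"),
  knowledge   = c("individual_id", "item_id", "component", "response")
)

.sex_levels <- c("female", "male", "unknown")
.component_levels <- c("question", "image", "freelist")

#' Assemble a validated foraging dataset
#'
#' Bundles the four entity tables (individuals, shellfish person-trips, trap
#' records, knowledge item responses) into a single validated object.  Any
#' table other than `individuals` may be empty.  Trait measurements
#' (`height` in cm, `grip` in kg-force, `knowledge` as a dimensionless latent
#' ability) may be `NA`; missingness is preserved and handled by the model's
#' imputation submodel, never dropped.
#'
#' @param individuals data frame with columns `individual_id`, `sex`
#'   (`"female"`, `"male"` or `"unknown"`), `age` (years), `height`, `grip`,
#'   `knowledge` (the last three may be `NA`).
#' @param shellfish data frame of person-trips with columns `individual_id`,
#'   `trip_id`, `returns_kg` (> 0), `duration_min` (> 0), `tide_height`
#'   (metres, may be negative after centring).
#' @param traps data frame of trap records with columns `trap_id`,
#'   `installer_id`, `trip_id`, `exposure_days` (> 0), `captures`
#'   (non-negative integer).
#' @param knowledge data frame of binary item responses with columns
#'   `individual_id`, `item_id`, `component` (`"question"`, `"image"` or
#'   `"freelist"`) and `response` (0/1).
#' @return An object of class `forage_data`.
#' @examples
#' d <- simulate_forage_data(preset = "table1", seed = 1)
#' summary(d)
#' @export
forage_data <- function(individuals,
                        shellfish = empty_shellfish(),
                        traps = empty_traps(),
                        knowledge = empty_knowledge()) {
  x <- structure(
    list(individuals = as.data.frame(individuals),
         shellfish   = as.data.frame(shellfish),
         traps       = as.data.frame(traps),
         knowledge   = as.data.frame(knowledge)),
    class = "forage_data")
  validate_forage_data(x)
  x
}

#' @rdname forage_data
#' @export
empty_individuals <- function() {
  data.frame(individual_id = character(), sex = character(), age = numeric(),
             height = numeric(), grip = numeric(), knowledge = numeric())
}

#' @rdname forage_data
#' @export
empty_shellfish <- function() {
  data.frame(individual_id = character(), trip_id = character(),
             returns_kg = numeric(), duration_min = numeric(),
             tide_height = numeric())
}

#' @rdname forage_data
#' @export
empty_traps <- function() {
  data.frame(trap_id = character(), installer_id = character(),
             trip_id = character(), exposure_days = numeric(),
             captures = integer())
}

#' @rdname forage_data
#' @export
empty_knowledge <- function() {
  data.frame(individual_id = character(), item_id = character(),
             component = character(), response = integer())
}

fail_rows <- function(table, rule, rows) {
  stop(sprintf("validation error in table '%s': rule '%s' violated at row(s) %s (%d row(s))",
               table, rule, paste(utils::head(rows, 10L), collapse = ", "),
               length(rows)), call. = FALSE)
}

check_rule <- function(bad, table, rule) {
  bad <- which(bad)
  if (length(bad)) fail_rows(table, rule, bad)
}

#' Validate a foraging dataset
#'
#' Checks every type invariant (positivity, uniqueness, binary coding,
#' referential integrity).  Validation is total: the first violated rule
#' raises an error naming the table, the rule and the offending row numbers.
#'
#' @param x a `forage_data` object (or a bare list with the same elements).
#' @return `x`, invisibly, if valid.
#' @export
validate_forage_data <- function(x) {
  ind <- x$individuals; sh <- x$shellfish; tr <- x$traps; kn <- x$knowledge
  for (tab in names(.forager_schema)) {
    d <- x[[tab]]
    missing_cols <- setdiff(.forager_schema[[tab]], names(d))
    if (length(missing_cols))
      stop(sprintf("table '%s' lacks column(s): %s", tab,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  check_rule(duplicated(ind$individual_id), "individuals", "individual_id unique")
  check_rule(!(ind$sex %in% .sex_levels), "individuals",
             "sex in {female, male, unknown}")
  check_rule(is.na(ind$age) | ind$age <= 0, "individuals", "age > 0")
  check_rule(!is.na(ind$height) & ind$height <= 0, "individuals",
             "height > 0 when present")
  check_rule(!is.na(ind$grip) & ind$grip <= 0, "individuals",
             "grip > 0 when present")

  if (nrow(sh)) {
    n_bad <- sum(is.na(sh$returns_kg) | sh$returns_kg <= 0)
    if (n_bad > 0)
      stop(sprintf("validation error in table 'shellfish': %d row(s) with returns_kg <= 0 or missing rejected (rows %s); only strictly positive returns are modelled",
                   n_bad,
                   paste(utils::head(which(is.na(sh$returns_kg) | sh$returns_kg <= 0), 10L),
                         collapse = ", ")), call. = FALSE)
    check_rule(is.na(sh$duration_min) | sh$duration_min <= 0, "shellfish",
               "duration_min > 0")
    check_rule(is.na(sh$tide_height), "shellfish", "tide_height present")
    check_rule(!(sh$individual_id %in% ind$individual_id), "shellfish",
               "individual_id refers to a known individual")
    # all person-trips of one trip share the trip-level covariates
    for (v in c("duration_min", "tide_height")) {
      spread <- tapply(sh[[v]], sh$trip_id, function(z) diff(range(z)))
      if (any(spread > 1e-9))
        fail_rows("shellfish", sprintf("%s constant within trip_id", v),
                  which(sh$trip_id %in% names(spread)[spread > 1e-9]))
    }
  }

  if (nrow(tr)) {
    check_rule(duplicated(tr$trap_id), "traps", "trap_id unique")
    check_rule(is.na(tr$exposure_days) | tr$exposure_days <= 0, "traps",
               "exposure_days > 0")
    check_rule(is.na(tr$captures) | tr$captures < 0 |
                 tr$captures != round(tr$captures), "traps",
               "captures a non-negative integer")
    check_rule(!(tr$installer_id %in% ind$individual_id), "traps",
               "installer_id refers to a known individual")
  }

  if (nrow(kn)) {
    check_rule(!(kn$component %in% .component_levels), "knowledge",
               "component in {question, image, freelist}")
    check_rule(!(kn$response %in% c(0L, 1L)), "knowledge",
               "response binary 0/1")
    check_rule(duplicated(kn[c("individual_id", "item_id")]), "knowledge",
               "one response per (individual, item)")
    check_rule(!(kn$individual_id %in% ind$individual_id), "knowledge",
               "individual_id refers to a known individual")
  }
  invisible(x)
}

#' Write a foraging dataset to a directory of CSV files
#'
#' One UTF-8 CSV per entity table (`individuals.csv`, `shellfish_obs.csv`,
#' `traps.csv`, `knowledge_responses.csv`); missing values are written as
#' empty fields.  `read_forage_data()` on the same directory is the identity.
#'
#' @param x a `forage_data` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_forage_data <- function(x, dir) {
  validate_forage_data(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(individuals = "individuals.csv", shellfish = "shellfish_obs.csv",
             traps = "traps.csv", knowledge = "knowledge_responses.csv")
  for (tab in names(files))
    utils::write.csv(x[[tab]], file.path(dir, files[[tab]]),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read a foraging dataset from CSV files
#'
#' Reads and validates the four entity tables.  `paths` is either a directory
#' containing the canonical file names used by [write_forage_data()], or a
#' named list/vector with elements `individuals`, `shellfish`, `traps`,
#' `knowledge` giving explicit file paths (any may be omitted).  `mapping`
#' adapts foreign column names, e.g. for deposited data whose headers differ
#' from the canonical schema.
#'
#' @param paths directory or named list of file paths.
#' @param mapping optional named list per table; each element is a named
#'   character vector `c(canonical = "foreign_column")`.
#' @return A validated `forage_data` object.
#' @export
read_forage_data <- function(paths, mapping = NULL) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- list(individuals = file.path(paths, "individuals.csv"),
                  shellfish   = file.path(paths, "shellfish_obs.csv"),
                  traps       = file.path(paths, "traps.csv"),
                  knowledge   = file.path(paths, "knowledge_responses.csv"))
    paths <- Filter(file.exists, paths)
  }
  read_one <- function(tab, empty) {
    p <- paths[[tab]]
    if (is.null(p)) return(empty)
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    d <- utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    m <- mapping[[tab]]
    if (!is.null(m)) {
      miss <- setdiff(unname(m), names(d))
      if (length(miss))
        stop(sprintf("mapped column(s) absent from %s: %s", p,
                     paste(miss, collapse = ", ")), call. = FALSE)
      names(d)[match(unname(m), names(d))] <- names(m)
    }
    keep <- intersect(names(empty), names(d))
    missing_cols <- setdiff(.forager_schema[[tab]], names(d))
    if (length(missing_cols))
      stop(sprintf("file %s lacks column(s): %s", p,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    for (col in names(empty))
      d[[col]] <- methods_as(d[[col]], empty[[col]])
    d[c(.forager_schema[[tab]], setdiff(names(d), .forager_schema[[tab]]))]
  }
  x <- structure(
    list(individuals = read_one("individuals", empty_individuals()),
         shellfish   = read_one("shellfish",   empty_shellfish()),
         traps       = read_one("traps",       empty_traps()),
         knowledge   = read_one("knowledge",   empty_knowledge())),
    class = "forage_data")
  validate_forage_data(x)
  x
}

# coerce a read column to the prototype's storage type (ids as character)
methods_as <- function(x, proto) {
  if (is.character(proto)) as.character(x)
  else if (is.integer(proto)) as.integer(x)
  else as.numeric(x)
}

#' Summarise a foraging dataset
#'
#' Reports, per resource, the number of participants, trips and outcome rows,
#' mean participant age, and the missingness fraction of each trait.
#'
#' @param object a `forage_data` object.
#' @param ... unused.
#' @return A list of class `summary.forage_data` with elements `shellfish`,
#'   `traps`, `knowledge` and `traits`.
#' @export
summary.forage_data <- function(object, ...) {
  ind <- object$individuals
  sh <- object$shellfish; tr <- object$traps; kn <- object$knowledge
  age_of <- function(ids) mean(ind$age[match(unique(ids), ind$individual_id)])
  out <- list(
    shellfish = list(
      participants = length(unique(sh$individual_id)),
      trips = length(unique(sh$trip_id)),
      outcomes = nrow(sh),
      mean_age = if (nrow(sh)) age_of(sh$individual_id) else NA_real_),
    traps = list(
      participants = length(unique(tr$installer_id)),
      trips = length(unique(tr$trip_id)),
      outcomes = nrow(tr),
      successes = if (nrow(tr)) sum(tr$captures > 0) else 0L,
      mean_age = if (nrow(tr)) age_of(tr$installer_id) else NA_real_),
    knowledge = list(
      respondents = length(unique(kn$individual_id)),
      items = length(unique(kn$item_id)),
      responses = nrow(kn)),
    traits = vapply(c("height", "grip", "knowledge"), function(v)
      if (nrow(ind)) mean(is.na(ind[[v]])) else NA_real_, numeric(1)))
  class(out) <- "summary.forage_data"
  out
}

#' @export
print.summary.forage_data <- function(x, ...) {
  cat("Foraging dataset summary\n")
  cat(sprintf("  shellfish: %d participants, %d trips, %d person-trips (mean age %.1f)\n",
              x$shellfish$participants, x$shellfish$trips, x$shellfish$outcomes,
              x$shellfish$mean_age))
  cat(sprintf("  traps:     %d installers, %d trips, %d traps, %d successful (mean age %.1f)\n",
              x$traps$participants, x$traps$trips, x$traps$outcomes,
              x$traps$successes, x$traps$mean_age))
  cat(sprintf("  knowledge: %d respondents x %d items (%d responses)\n",
              x$knowledge$respondents, x$knowledge$items, x$knowledge$responses))
  cat(sprintf("  trait missingness: height %.2f, grip %.2f, knowledge %.2f\n",
              x$traits[["height"]], x$traits[["grip"]], x$traits[["knowledge"]]))
  invisible(x)
}

#' @export
print.forage_data <- function(x, ...) {
  cat(sprintf("<forage_data: %d individuals, %d shellfish person-trips, %d traps, %d knowledge responses>\n",
              nrow(x$individuals), nrow(x$shellfish), nrow(x$traps),
              nrow(x$knowledge)))
  invisible(x)
}
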