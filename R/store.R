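# On-disk case store: one directory per dataset, one serialized file per
# case, plus a JSON manifest carrying the schema version, generation seed
# and configuration hash. Writes are atomic per case, so a partially
# generated dataset can be resumed or regenerated case by case.

STORE_SCHEMA_VERSION <- 1L

#' Open or create a case store
#'
#' @param path Directory for the dataset.
#' @param create Create the directory and manifest if missing.
#' @param seed,config Provenance recorded in the manifest at creation time
#'   (`config` is hashed with [config_hash()]).
#' @return Object of class `case_store`.
#' @export
case_store <- function(path, create = TRUE, seed = NA_integer_,
                       config = NULL) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    if (!create)
      stop(sprintf("no case store at '%s'", path), call. = FALSE)
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(schema_version = STORE_SCHEMA_VERSION,
                     seed = seed,
                     config_hash = if (is.null(config)) NA_character_
                                   else config_hash(config),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  }
  manifest <- jsonlite::read_json(mf)
  if (!identical(as.integer(manifest$schema_version), STORE_SCHEMA_VERSION))
    stop(sprintf("store schema version %s != supported %d",
                 manifest$schema_version, STORE_SCHEMA_VERSION),
         call. = FALSE)
  st <- list(path = path, manifest = manifest)
  class(st) <- "case_store"
  st
}

#' @export
print.case_store <- function(x, ...) {
  cat(sprintf("Case store at '%s': %d cases (schema v%s, config %s)\n",
              x$path, length(case_ids(x)), x$manifest$schema_version,
              substr(as.character(x$manifest$config_hash), 1, 8)))
  invisible(x)
}

case_file <- function(store, case_id) file.path(store$path,
                                                paste0(case_id, ".rds"))

#' Save a case to a store
#'
#' Persists the phantom together with any simulated signals and
#' preprocessed input map. Arrays round-trip losslessly.
#'
#' @param store A [case_store()].
#' @param case A `phantom_case`.
#' @param signals Optional `signal_tensor`.
#' @param input_map Optional preprocessed input map.
#' @return The case id, invisibly.
#' @export
save_case <- function(store, case, signals = NULL, input_map = NULL) {
  rec <- list(schema_version = STORE_SCHEMA_VERSION, case = case,
              signals = signals, input_map = input_map)
  f <- case_file(store, case$case_id)
  tmp <- paste0(f, ".tmp")
  saveRDS(rec, tmp)
  file.rename(tmp, f)
  invisible(case$case_id)
}

#' Load a case from a store
#'
#' @param store A [case_store()].
#' @param case_id Case identifier.
#' @param require Character vector of datasets that must be present
#'   (`"signals"`, `"input_map"`); a missing one raises a format error
#'   naming it.
#' @return List with `case`, `signals`, `input_map`.
#' @export
load_case <- function(store, case_id, require = character(0)) {
  f <- case_file(store, case_id)
  if (!file.exists(f))
    stop(sprintf("no case '%s' in store", case_id), call. = FALSE)
  rec <- readRDS(f)
  if (!identical(as.integer(rec$schema_version), STORE_SCHEMA_VERSION))
    stop(sprintf("case '%s': schema version mismatch", case_id),
         call. = FALSE)
  for (nm in require)
    if (is.null(rec[[nm]]))
      stop(sprintf("case '%s': missing dataset '%s'", case_id, nm),
           call. = FALSE)
  rec
}

#' List case ids in a store
#' @param store A [case_store()].
#' @return Character vector of ids, sorted.
#' @export
case_ids <- function(store) {
  f <- list.files(store$path, pattern = "^case_.*\\.rds$")
  sort(sub("\\.rds$", "", f))
}

#' Split case ids into training and testing sets
#'
#' Seeded shuffle followed by partition, as in the reference protocol
#' (24,000 train / 1,000 test out of 25,000 at full scale). Deterministic:
#' the same ids and seed always give the same manifest.
#'
#' @param ids Character vector of case ids.
#' @param n_train,n_test Exact counts; must sum to `length(ids)`.
#'   Alternatively give `train_fraction`.
#' @param train_fraction Fraction assigned to training (used when counts
#'   are missing); `1.0` gives an empty test set.
#' @param seed Integer seed for the shuffle.
#' @return Object of class `dataset_manifest` with `case_ids` (shuffled
#'   order), `split_assignment` (named character vector, `"train"` /
#'   `"test"`), `seed`, `n_train`, `n_test`.
#' @export
split_dataset <- function(ids, n_train = NULL, n_test = NULL,
                          train_fraction = NULL, seed = 1) {
  n <- length(ids)
  if (is.null(n_train)) {
    if (is.null(train_fraction))
      stop("give n_train/n_test or train_fraction", call. = FALSE)
    n_train <- round(n * train_fraction)
    n_test <- n - n_train
  }
  if (is.null(n_test)) n_test <- n - n_train
  if (n_train + n_test != n || n_train < 0 || n_test < 0)
    stop(sprintf("inconsistent split: %d train + %d test != %d cases",
                 n_train, n_test, n), call. = FALSE)
  shuffled <- with_seed(seed, sample(ids))
  assignment <- c(rep("train", n_train), rep("test", n_test))
  names(assignment) <- shuffled
  m <- list(case_ids = shuffled, split_assignment = assignment,
            seed = as.integer(seed), n_train = as.integer(n_train),
            n_test = as.integer(n_test))
  class(m) <- "dataset_manifest"
  m
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("Dataset split: %d train / %d test (seed %d)\n",
              x$n_train, x$n_test, x$seed))
  invisible(x)
}

#' Export a trace as two-column ASCII
#'
#' Writes `(time_s, ez)` pairs for external inspection.
#'
#' @param trace Numeric vector of field samples.
#' @param dt Sample interval, s.
#' @param path Output file.
#' @export
export_trace_ascii <- function(trace, dt, path) {
  df <- data.frame(time_s = (seq_along(trace) - 1) * dt, ez = trace)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
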