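#' Analysis configuration
#'
#' Collects every knob the pipeline honours: the isotope constants, the base
#' of the sponge-allometry logarithm, the background strategy for tracer
#' fluxes, and the Dunn adjustment method. Unknown keys in a config file are
#' rejected rather than silently ignored.
#'
#' @param constants An [iso_constants()] object.
#' @param log_base Base of the AFDM allometry logarithm, 10 or `exp(1)`.
#' @param background_strategy `"start_sample"` (default: the start sample of
#'   each chamber defines the unenriched background for that chamber's
#'   tracer fluxes) or `"fixed"` (use `fixed_background_delta13c`).
#' @param fixed_background_delta13c Named list (`dic`, `poc`) of background
#'   delta-13C used when `background_strategy = "fixed"`.
#' @param background_delta13c_override Single tissue background delta-13C
#'   overriding the unfed-conspecific mean, or `NULL`.
#' @param dunn_adjust p-adjustment method for Dunn post-hoc comparisons.
#' @param o2_saturation_min Saturation floor retained for reuse on data
#'   logged past the design's stopping rule; the default 0 applies no
#'   filter.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(constants = iso_constants(),
                            log_base = 10,
                            background_strategy = c("start_sample", "fixed"),
                            fixed_background_delta13c = list(dic = 0.5,
                                                             poc = -24),
                            background_delta13c_override = NULL,
                            dunn_adjust = "holm",
                            o2_saturation_min = 0) {
  background_strategy <- match.arg(background_strategy)
  structure(list(constants = constants, log_base = log_base,
                 background_strategy = background_strategy,
                 fixed_background_delta13c = fixed_background_delta13c,
                 background_delta13c_override = background_delta13c_override,
                 dunn_adjust = dunn_adjust,
                 o2_saturation_min = o2_saturation_min),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys: `r_vpdb`, `respiratory_quotient`, `log_base`,
#' `background_strategy`, `dunn_adjust`, `o2_saturation_min`. Any other key
#' is an error.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("r_vpdb", "respiratory_quotient", "log_base",
             "background_strategy", "dunn_adjust", "o2_saturation_min")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cst <- iso_constants(
    r_vpdb = cfg$r_vpdb %||% 0.0111802,
    respiratory_quotient = cfg$respiratory_quotient %||% 1.0)
  pipeline_config(
    constants = cst,
    log_base = cfg$log_base %||% 10,
    background_strategy = cfg$background_strategy %||% "start_sample",
    dunn_adjust = cfg$dunn_adjust %||% "holm",
    o2_saturation_min = cfg$o2_saturation_min %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_schemas <- list(
  specimens = c("id", "taxon", "volume_ml", "tissue_oc_mol",
                "tissue_delta13c", "is_background", "substrate_batch_id",
                "feeding_hours", "feeding_volume_l"),
  batches = c("id", "kind", "concentration_um", "atom_fraction"),
  incubations = c("chamber_id", "specimen_id", "role", "condition",
                  "chamber_volume_l", "duration_h", "dic_start_um",
                  "dic_end_um", "dic_d13c_start", "dic_d13c_end",
                  "doc_start_um", "doc_end_um", "poc_start_um",
                  "poc_end_um", "poc_d13c_start", "poc_d13c_end",
                  "start_strategy", "refill_volume_l", "refill_dic_um",
                  "refill_doc_um", "refill_poc_um"),
  o2_series = c("chamber_id", "specimen_id", "time_h", "o2_um")
)

#' Write a dataset to a directory of CSV files
#'
#' One file per table (`specimens.csv`, `batches.csv`, `incubations.csv`,
#' `o2_series.csv`, and `ground_truth.csv` when present), comma-separated,
#' header row, UTF-8, period decimals, empty string for missing values.
#' Each file starts with a `#` provenance header naming the package version
#' and the constants in force.
#'
#' @param dataset Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @param constants An [iso_constants()] object recorded in the header.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, constants = iso_constants()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset)) {
    if (!is.data.frame(dataset[[nm]])) next
    write_table_csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
                    constants)
  }
  invisible(dir)
}

write_table_csv <- function(df, path, constants = iso_constants()) {
  header <- sprintf(
    "# isoflux %s | r_vpdb=%.7f respiratory_quotient=%g",
    as.character(utils::packageVersion("isoflux")),
    constants$r_vpdb, constants$respiratory_quotient)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a dataset directory
#'
#' Reads the CSV tables written by [write_dataset()] (or prepared by hand in
#' the same schemas), checks required columns, and validates
#' cross-references: every fed specimen must name an existing substrate
#' batch, every animal chamber an existing specimen, and control chambers
#' must leave `specimen_id` empty. Errors name the offending file and row.
#'
#' @param dir Directory containing `specimens.csv`, `batches.csv`,
#'   `incubations.csv`, `o2_series.csv` (and optionally
#'   `ground_truth.csv` / `foodchain.csv`).
#' @return Named list of data.frames.
#' @export
read_tables <- function(dir) {
  read1 <- function(nm, required = TRUE) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) {
      if (required) stop("missing table: ", p, call. = FALSE)
      return(NULL)
    }
    df <- utils::read.csv(p, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
    if (!is.null(df)) {
      # columns that are entirely missing parse as logical; the schemas
      # only ever hold numbers or strings there
      all_na <- vapply(df, function(col) is.logical(col) && all(is.na(col)),
                       TRUE)
      df[all_na] <- lapply(df[all_na], as.numeric)
    }
    if (nm %in% names(dataset_schemas)) {
      miss <- setdiff(dataset_schemas[[nm]], names(df))
      if (length(miss) > 0L) {
        stop(sprintf("schema violation in %s: missing column(s) %s",
                     basename(p), paste(miss, collapse = ", ")),
             call. = FALSE)
      }
    }
    df
  }
  ds <- list(specimens = read1("specimens"), batches = read1("batches"),
             incubations = read1("incubations"),
             o2_series = read1("o2_series"),
             ground_truth = read1("ground_truth", required = FALSE),
             foodchain = read1("foodchain", required = FALSE))
  # empty-string missing convention for id-like columns
  for (cc in c("specimen_id", "substrate_batch_id")) {
    for (tb in c("specimens", "incubations")) {
      if (cc %in% names(ds[[tb]])) {
        ds[[tb]][[cc]][is.na(ds[[tb]][[cc]])] <- ""
      }
    }
  }
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  sp <- ds$specimens; inc <- ds$incubations
  fed <- !sp$is_background
  bad <- which(fed & !nzchar(sp$substrate_batch_id))
  if (length(bad) > 0L) {
    stop(sprintf("link error in specimens.csv row %d: fed specimen '%s' %s",
                 bad[1L], sp$id[bad[1L]], "has no substrate_batch_id"),
         call. = FALSE)
  }
  dangle <- which(fed & !(sp$substrate_batch_id %in% ds$batches$id))
  if (length(dangle) > 0L) {
    stop(sprintf("link error in specimens.csv row %d: unknown batch '%s'",
                 dangle[1L], sp$substrate_batch_id[dangle[1L]]),
         call. = FALSE)
  }
  ctrl_with_id <- which(inc$role == "control" & nzchar(inc$specimen_id))
  if (length(ctrl_with_id) > 0L) {
    stop(sprintf(
      "validation error in incubations.csv row %d: control chamber '%s' %s",
      ctrl_with_id[1L], inc$chamber_id[ctrl_with_id[1L]],
      "must not reference a specimen"), call. = FALSE)
  }
  an_dangle <- which(inc$role == "animal" & !(inc$specimen_id %in% sp$id))
  if (length(an_dangle) > 0L) {
    stop(sprintf("link error in incubations.csv row %d: unknown specimen %s",
                 an_dangle[1L], sprintf("'%s'",
                                        inc$specimen_id[an_dangle[1L]])),
         call. = FALSE)
  }
  o2_dangle <- setdiff(inc$chamber_id, ds$o2_series$chamber_id)
  if (length(o2_dangle) > 0L) {
    stop("link error: no O2 series for chamber(s) ",
         paste(o2_dangle, collapse = ", "), call. = FALSE)
  }
  invisible(ds)
}

#' Write pipeline results with provenance headers
#'
#' Writes `budget.csv` and `stats.csv` (and `fluxes.csv`) under `dir`.
#'
#' @param result List from [run_pipeline()].
#' @param dir Output directory.
#' @param config The [pipeline_config()] used, recorded in the headers.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, config = pipeline_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(result$budget, file.path(dir, "budget.csv"),
                  config$constants)
  if (!is.null(result$stats) && nrow(result$stats) > 0L) {
    write_table_csv(result$stats, file.path(dir, "stats.csv"),
                    config$constants)
  }
  if (!is.null(result$fluxes)) {
    write_table_csv(result$fluxes$animals, file.path(dir, "fluxes.csv"),
                    config$constants)
  }
  invisible(dir)
}
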