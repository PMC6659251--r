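#' Write a registry to a directory of CSV files
#'
#' Writes the five registry tables as comma-separated UTF-8 files with a
#' header row (`patients.csv`, `stays.csv`, `diagnoses.csv`, `adl.csv`,
#' `deaths.csv`). The ground-truth component of a synthetic registry is
#' deliberately withheld: the files contain only what a real discharge
#' registry would.
#'
#' @param registry a `"registry"` object (see [generate_registry()],
#'   [read_registry()]).
#' @param directory output directory, created if missing.
#' @return invisibly, the vector of file paths written.
#' @export
write_registry <- function(registry, directory) {
  stopifnot(inherits(registry, "registry"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tab in registry_table_names()) {
    p <- file.path(directory, paste0(tab, ".csv"))
    utils::write.csv(registry[[tab]], p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

registry_table_names <- function() c("patients", "stays", "diagnoses", "adl", "deaths")

#' Read a registry from a directory of CSV files
#'
#' @param directory directory holding the five CSV files written by
#'   [write_registry()].
#' @return a `"registry"` object with `truth = NULL`.
#' @export
read_registry <- function(directory) {
  out <- lapply(registry_table_names(), function(tab) {
    p <- file.path(directory, paste0(tab, ".csv"))
    if (!file.exists(p)) stop("missing registry file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  })
  names(out) <- registry_table_names()
  out$truth <- NULL
  class(out) <- "registry"
  out
}

#' Validate registry invariants
#'
#' Checks referential integrity and value constraints of the five registry
#' tables: every stay references an existing patient; every diagnosis
#' references an existing stay; ADL rows reference post-acute stays of the
#' same patient; ADL scores lie in 0-3; days are non-negative integers;
#' stay discharge is not before admission; at most one death per patient,
#' not before the patient's first admission day.
#'
#' @param registry a `"registry"` object or a directory path readable by
#'   [read_registry()].
#' @return a data frame of violations with columns `table`, `row`, `rule`;
#'   zero rows when the registry is clean.
#' @export
validate_registry <- function(registry) {
  if (is.character(registry)) registry <- read_registry(registry)
  stopifnot(inherits(registry, "registry"))
  v <- list()
  note <- function(table, rows, rule) {
    if (length(rows))
      v[[length(v) + 1L]] <<- data.frame(table = table, row = rows, rule = rule)
  }
  with(registry, {
    note("stays", which(!(stays$patient_id %in% patients$patient_id)),
         "stay references missing patient")
    note("stays", which(stays$discharge_day < stays$admission_day),
         "discharge before admission")
    note("stays", which(stays$admission_day < 0), "negative admission day")
    note("diagnoses", which(!(diagnoses$stay_id %in% stays$stay_id)),
         "diagnosis references missing stay")
    note("diagnoses", which(!diagnoses$position %in% c("primary", "associated")),
         "invalid diagnosis position")
    if (nrow(adl)) {
      sc <- as.matrix(adl[, paste0("adl", 1:6)])
      note("adl", which(rowSums(sc < 0 | sc > 3 | sc != floor(sc)) > 0),
           "ADL score outside 0-3")
      m <- match(adl$stay_id, stays$stay_id)
      note("adl", which(is.na(m)), "ADL references missing stay")
      ok <- !is.na(m)
      note("adl", which(ok)[stays$care_type[m[ok]] != "post_acute"],
           "ADL attached to non-post-acute stay")
      note("adl", which(ok)[adl$patient_id[ok] != stays$patient_id[m[ok]]],
           "ADL patient differs from stay patient")
      note("adl", which(ok)[adl$day[ok] < stays$admission_day[m[ok]] |
                              adl$day[ok] > stays$discharge_day[m[ok]]],
           "ADL day outside its stay")
    }
    if (nrow(deaths)) {
      note("deaths", which(duplicated(deaths$patient_id)), "duplicate death record")
      first_adm <- tapply(stays$admission_day, stays$patient_id, min)
      fa <- first_adm[as.character(deaths$patient_id)]
      note("deaths", which(!is.na(fa) & deaths$day < fa),
           "death before first admission")
    }
  })
  if (length(v)) do.call(rbind, v)
  else data.frame(table = character(), row = integer(), rule = character())
}
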