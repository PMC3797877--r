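#' @include AllClasses.R
NULL

# dialect: comma-separated, UTF-8, "NA" missing marker for phenotypes,
# allele code 0 missing marker for genotypes (GenAlEx convention)

.labelColsPheno <- c("plant", "region", "population", "family", "treatment", "diameter")

#' Read a per-plant phenotype CSV
#'
#' Expects a header row with the label columns `plant`, `region`,
#' `population`, `family`, `treatment`, `diameter` and one numeric column
#' per trait; `NA` marks a missing value. Labels are validated against the
#' design; unknown populations and non-numeric trait cells are errors
#' naming the offending row and column.
#'
#' @param path CSV file path.
#' @param design a [StudyDesign-class].
#' @param traits trait column names; default: every non-label column.
#' @return a [PhenotypeTable-class].
#' @seealso [writePhenotypes()]
#' @export
readPhenotypes <- function(path, design, traits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  miss <- setdiff(.labelColsPheno, names(raw))
  if (length(miss)) {
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (is.null(traits)) traits <- setdiff(names(raw), .labelColsPheno)
  if (nrow(raw) == 0) {
    warning("phenotype file '", path, "' has 0 data rows")
    for (col in c("diameter", traits)) raw[[col]] <- numeric(0)
    return(PhenotypeTable(raw, design, traits = traits))
  }
  bad <- setdiff(unique(raw$population), design@populations$population)
  if (length(bad)) {
    stop("unknown population(s) not in design: ", paste(bad, collapse = ", "))
  }
  for (col in c("diameter", traits)) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    badcell <- which(is.na(num) & !(is.na(v) | v %in% c("NA", "")))
    if (length(badcell)) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   v[badcell[1]], col, badcell[1]))
    }
    raw[[col]] <- num
  }
  PhenotypeTable(raw, design, traits = traits)
}

#' Read a codominant genotype CSV (GenAlEx-style layout)
#'
#' Expects columns `individual`, `region`, `population` followed by an even
#' number of integer allele-code columns, two per locus. Allele code 0
#' marks a missing copy; a locus is missing iff both copies are 0.
#'
#' @param path CSV file path.
#' @param design a [StudyDesign-class].
#' @return a [GenotypeTable-class]. Per-locus missingness is reported via
#'   `message()`.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  lab <- c("individual", "region", "population")
  miss <- setdiff(lab, names(raw))
  if (length(miss)) {
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  }
  ac <- setdiff(names(raw), lab)
  if (length(ac) %% 2 != 0) {
    stop("odd number of allele columns (", length(ac),
         "): need exactly two per locus")
  }
  if (length(ac) == 0) stop("no allele columns: at least one locus required")
  for (cc in ac) {
    v <- raw[[cc]]
    if (!is.numeric(v)) stop("allele column '", cc, "' is not numeric")
    if (any(v < 0, na.rm = TRUE)) stop("negative allele code in column '", cc, "'")
    raw[[cc]] <- as.integer(v)
  }
  loci <- unique(sub("\\.[12]$", "", ac))
  if (length(loci) * 2 != length(ac)) {
    # headers not in '<locus>.1/.2' form: pair consecutive columns
    loci <- paste0("L", seq_len(length(ac) / 2))
    names(raw)[match(ac, names(raw))] <-
      as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  }
  gt <- GenotypeTable(raw, design, loci = loci)
  missRate <- vapply(loci, function(loc) mean(gt@data[[paste0(loc, ".1")]] == 0),
                     numeric(1))
  message("per-locus missingness: ",
          paste(sprintf("%s=%.1f%%", loci, 100 * missRate), collapse = ", "))
  gt
}

#' Write phenotype / genotype tables in the package CSV dialect
#'
#' Writing then reading reproduces the object exactly (round-trip
#' contract); reruns are byte-identical for identical objects.
#'
#' @param x a [PhenotypeTable-class] or [GenotypeTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(x, path) {
  stopifnot(methods::is(x, "PhenotypeTable"))
  d <- x@data[, c(.labelColsPheno, x@traits), drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(methods::is(x, "GenotypeTable"))
  cols <- c("individual", "region", "population",
            as.vector(rbind(paste0(x@loci, ".1"), paste0(x@loci, ".2"))))
  utils::write.csv(x@data[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes one CSV per named table plus `manifest.json` recording the
#' configuration, the seed, and MD5 checksums of any input files. Output is
#' deterministic: rerunning with the same tables, config and seed produces
#' byte-identical files.
#'
#' @param tables named list of `data.frame`s.
#' @param path output directory (created if needed).
#' @param config optional named list recorded in the manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @param inputs optional character vector of input file paths to checksum.
#' @return the directory path, invisibly.
#' @export
writeResults <- function(tables, path, config = NULL, seed = NULL, inputs = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  for (nm in names(tables)) {
    utils::write.csv(as.data.frame(tables[[nm]]),
                     file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  }
  manifest <- list(
    config = config,
    seed = seed,
    tables = names(tables),
    input_checksums = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else NULL
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
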