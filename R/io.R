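# CSV dialects (one per modality), FASTA ingest, Beer-Lambert helper and
# JSON analysis reports. Files speak degrees Celsius; objects hold kelvin.

CSV_HEADERS <- list(
  dsc = c("temperature_C", "cp_kJ_per_mol_K"),
  ppc = c("temperature_C", "dQ_J", "role"),
  cd = c("wavelength_nm", "ellipticity_mdeg"),
  osmolyte = c("glycerol_pct_wv", "tm_C", "dH_kJ_per_mol"))

#' Read an instrument-trace CSV
#'
#' Parses one of the package's CSV dialects into its typed object,
#' converting temperatures from degrees Celsius to kelvin on ingest:
#' \describe{
#'   \item{dsc}{`temperature_C,cp_kJ_per_mol_K` -> [thermogram()]}
#'   \item{ppc}{`temperature_C,dQ_J,role` -> list of [ppc_scan()]s split by
#'     role (pulse metadata supplied via `dP`, `m_s`, `V_s`)}
#'   \item{cd}{`wavelength_nm,ellipticity_mdeg` -> [cd_spectrum()]}
#'   \item{osmolyte}{`glycerol_pct_wv,tm_C,dH_kJ_per_mol` ->
#'     [osmolyte_series()]}
#' }
#' A malformed header or non-numeric row fails with the offending line
#' number; non-monotone temperature grids fail validation.
#'
#' @param path CSV file path.
#' @param kind one of `"dsc"`, `"ppc"`, `"cd"`, `"osmolyte"`.
#' @param dP,m_s,V_s pulse metadata applied to PPC scans (see
#'   [ppc_scan()]).
#' @param ... extra arguments passed to the object constructor (e.g.
#'   `strand_conc` for DSC, `dH_ref`/`T_ref` for osmolyte series).
#' @return The typed object for `kind`.
#' @export
read_curve_csv <- function(path, kind = c("dsc", "ppc", "cd", "osmolyte"),
                           dP = psi_to_pa(70), m_s = NA_real_, V_s = NA_real_,
                           ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  expect <- CSV_HEADERS[[kind]]
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) < length(expect) ||
      !identical(header[seq_along(expect)], expect))
    stop(sprintf("line 1: expected header '%s', found '%s'",
                 paste(expect, collapse = ","),
                 paste(header, collapse = ",")))
  df <- read.csv(path, stringsAsFactors = FALSE)
  num_cols <- setdiff(expect, "role")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("line %d: non-numeric value in column '%s'", bad + 1L, cl))
    }
  }
  switch(kind,
    dsc = thermogram(celsius_to_kelvin(df$temperature_C),
                     df$cp_kJ_per_mol_K, ...),
    ppc = {
      scans <- lapply(split(df, df$role), function(d) {
        d <- d[order(d$temperature_C), , drop = FALSE]
        ppc_scan(celsius_to_kelvin(d$temperature_C), d$dQ_J, dP = dP,
                 role = d$role[1],
                 m_s = if (d$role[1] == "sample_buffer") m_s else NA_real_,
                 V_s = if (d$role[1] == "sample_buffer") V_s else NA_real_)
      })
      unname(scans)
    },
    cd = cd_spectrum(df$wavelength_nm, df$ellipticity_mdeg),
    osmolyte = osmolyte_series(df$glycerol_pct_wv,
                               celsius_to_kelvin(df$tm_C),
                               dH = df$dH_kJ_per_mol, ...))
}

fmt6 <- function(x) formatC(x, digits = 6, format = "g")

#' Write an instrument trace to its CSV dialect
#'
#' Inverse of [read_curve_csv()]: values are written at 6 significant
#' digits with temperatures in degrees Celsius, so a write/read cycle
#' reproduces values to that precision and a second write reproduces the
#' file text exactly.
#'
#' @param x a [thermogram()], [cd_spectrum()], [osmolyte_series()], or a
#'   [ppc_scan()] / list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  lines <- if (inherits(x, "thermogram")) {
    c(paste(CSV_HEADERS$dsc, collapse = ","),
      paste(fmt6(kelvin_to_celsius(x$T)), fmt6(x$Cp), sep = ","))
  } else if (inherits(x, "cd_spectrum")) {
    c(paste(CSV_HEADERS$cd, collapse = ","),
      paste(fmt6(x$wavelength), fmt6(x$ellipticity), sep = ","))
  } else if (inherits(x, "osmolyte_series")) {
    c(paste(CSV_HEADERS$osmolyte, collapse = ","),
      paste(fmt6(x$points$glycerol_pct_wv),
            fmt6(kelvin_to_celsius(x$points$Tm)),
            fmt6(x$points$dH), sep = ","))
  } else if (inherits(x, "ppc_scan") ||
             (is.list(x) && all(vapply(x, inherits, logical(1), "ppc_scan")))) {
    scans <- if (inherits(x, "ppc_scan")) list(x) else x
    body <- unlist(lapply(scans, function(s)
      paste(fmt6(kelvin_to_celsius(s$T)), fmt6(s$dQ), s$role, sep = ",")))
    c(paste(CSV_HEADERS$ppc, collapse = ","), body)
  } else stop("unsupported object type for CSV export")
  writeLines(lines, path)
  invisible(path)
}

#' DNA strand record
#'
#' A named DNA sequence with its molar extinction coefficient at 260 nm.
#' Sequences are validated over the unambiguous DNA alphabet and
#' upper-cased on construction.
#'
#' @param name record name.
#' @param sequence DNA string over A/C/G/T (case-insensitive).
#' @param extinction_260 molar extinction coefficient at 260 nm,
#'   1/(mol cm) (user-supplied, e.g. 228500 for the 22-mer human telomeric
#'   strand).
#' @return An object of class `"strand_record"`.
#' @export
strand_record <- function(name, sequence, extinction_260 = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains non-DNA characters (A/C/G/T only)")
  structure(list(name = name, sequence = sequence,
                 extinction_260 = extinction_260),
            class = "strand_record")
}

#' @export
print.strand_record <- function(x, ...) {
  cat(sprintf("strand %s: %d nt%s\n  5'-%s-3'\n", x$name, nchar(x$sequence),
              if (is.finite(x$extinction_260))
                sprintf(", eps260 = %g /(M cm)", x$extinction_260) else "",
              x$sequence))
  invisible(x)
}

#' Read DNA strands from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning validated
#' [strand_record()]s. Sequences must be literal (repeat shorthand is not
#' expanded) and are upper-cased; non-A/C/G/T characters fail validation.
#' Extinction coefficients can be attached by name.
#'
#' @param path FASTA file path.
#' @param extinction optional named numeric vector of 260 nm extinction
#'   coefficients, matched to record names.
#' @return List of [strand_record()]s (empty for an empty file).
#' @export
read_strands_fasta <- function(path, extinction = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!any(grepl("^>", readLines(path, warn = FALSE)))) return(list())
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    eps <- if (!is.null(extinction) && nm %in% names(extinction))
      unname(extinction[nm]) else NA_real_
    strand_record(nm, as.character(set[[i]]), eps)
  })
}

#' Strand concentration by Beer-Lambert
#'
#' `c = A260 / (eps * l)`.
#'
#' @param A260 absorbance at 260 nm (>= 0).
#' @param record a [strand_record()] with a finite `extinction_260`, or a
#'   numeric extinction coefficient, 1/(mol cm).
#' @param path_cm optical path length, cm (> 0).
#' @return Strand concentration, mol/L.
#' @examples
#' strand_concentration(1.1425, 228500)   # 5 uM working concentration
#' @export
strand_concentration <- function(A260, record, path_cm = 1) {
  eps <- if (inherits(record, "strand_record")) record$extinction_260
         else record
  stopifnot(is.numeric(A260), length(A260) == 1L, A260 >= 0,
            is.numeric(path_cm), length(path_cm) == 1L, path_cm > 0)
  if (!is.finite(eps) || eps == 0)
    stop("extinction coefficient must be non-zero and finite")
  A260 / (eps * path_cm)
}

#' Assemble and serialise an analysis report
#'
#' Bundles per-module results with provenance (package version, seed,
#' configuration, input digests) into a schema-versioned list that
#' round-trips through JSON without loss.
#'
#' @param results named list of result values (numbers, vectors, nested
#'   named lists).
#' @param inputs named character vector/list describing the inputs (paths
#'   or digests).
#' @param seed seed used for any randomness.
#' @param config optional named list of settings.
#' @return An object of class `"analysis_report"`.
#' @export
analysis_report <- function(results, inputs = list(), seed = NA_integer_,
                            config = list()) {
  structure(list(schema_version = 1L,
                 tool = "quadcal",
                 version = as.character(utils::packageVersion("quadcal")),
                 seed = seed,
                 inputs = inputs,
                 config = config,
                 results = results),
            class = "analysis_report")
}

#' @param report an `"analysis_report"`.
#' @param path output JSON path.
#' @rdname analysis_report
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname analysis_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(obj) <- "analysis_report"
  obj
}
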