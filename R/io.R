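# File dialects: strict TSV readers/writers and JSON/markdown reports.
#
# All tables are UTF-8, tab-separated, one header row, `#` comment lines
# ignored. Parsing is strict: malformed rows are errors carrying file and
# line number; unknown columns only warn.

read_tsv_rows <- function(path, required, optional = character()) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    abort_validation(sprintf("%s: empty file (no header row)", path))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    abort_validation(sprintf("%s:%d: missing required column(s): %s",
                             path, lineno[1L],
                             paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(header, c(required, optional))
  if (length(unknown)) {
    warn_mosaicsat(sprintf("%s: ignoring unknown column(s): %s",
                           path, paste(unknown, collapse = ", ")))
  }
  if (length(lines) < 2L) {
    abort_validation(sprintf("%s: no data rows", path))
  }
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; restore it so empty last columns parse
  ends_tab <- endsWith(lines[-1L], "\t")
  cells[ends_tab] <- lapply(cells[ends_tab], function(x) c(x, ""))
  nfield <- lengths(cells)
  bad <- which(nfield != length(header))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s:%d: expected %d tab-separated fields, found %d",
      path, lineno[-1L][bad[1L]], length(header), nfield[bad[1L]]))
  }
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- header
  df <- df[intersect(c(required, optional), header)]
  attr(df, "linenos") <- lineno[-1L]
  df
}

parse_count_column <- function(x, path, linenos, column) {
  n <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(n) | abs(n - round(n)) > 1e-8)
  if (length(bad)) {
    abort_validation(sprintf("%s:%d: column `%s` must be an integer (got '%s')",
                             path, linenos[bad[1L]], column, x[bad[1L]]))
  }
  as.integer(round(n))
}

#' Read an allele spectrum from TSV
#'
#' Accepts either the wide dialect (`locus_id`, `n_alleles`: one row per
#' locus) or the long dialect (`mutation_id`, `locus_id`: one row per
#' mutation, aggregated on read). Lines starting with `#` are comments.
#'
#' @param path Path to a TSV file.
#' @return An [allele_spectrum()].
#' @examples
#' read_spectrum(mosaicsat_example("table1_spectrum.tsv"))
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  first <- readLines(path, n = 50L, encoding = "UTF-8", warn = FALSE)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  if (!length(first)) abort_validation(sprintf("%s: empty file (no header row)", path))
  header <- strsplit(first[1L], "\t", fixed = TRUE)[[1L]]
  if ("n_alleles" %in% header) {
    df <- read_tsv_rows(path, required = c("locus_id", "n_alleles"))
    counts <- parse_count_column(df$n_alleles, path, attr(df, "linenos"),
                                 "n_alleles")
    allele_spectrum(counts, df$locus_id)
  } else if ("mutation_id" %in% header) {
    df <- read_tsv_rows(path, required = c("mutation_id", "locus_id"))
    if (anyDuplicated(df$mutation_id)) {
      abort_validation(sprintf("%s: duplicated mutation_id '%s'", path,
                               df$mutation_id[duplicated(df$mutation_id)][1L]))
    }
    counts <- table(df$locus_id)
    allele_spectrum(as.integer(counts), names(counts))
  } else {
    abort_validation(sprintf(
      "%s: header must contain either `locus_id`+`n_alleles` or `mutation_id`+`locus_id`",
      path))
  }
}

#' Write an allele spectrum to TSV
#'
#' Emits the wide dialect (`locus_id`, `n_alleles`), byte-stable for a given
#' spectrum: loci in stored order, LF line endings.
#'
#' @param spectrum An [allele_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "allele_spectrum"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("locus_id\tn_alleles",
               sprintf("%s\t%d", spectrum$locus_id, spectrum$n_alleles)),
             con, sep = "\n")
  invisible(path)
}

#' Read a pairwise complementation matrix from TSV
#'
#' Long dialect: columns `mutation_a`, `mutation_b`, `result`
#' (`complements` | `fails` | `partial` | `untested`), optional `channel`.
#'
#' @param path Path to a TSV file.
#' @param deficiencies Optional path to a deficiency-test TSV (columns
#'   `mutation`, `deficiency_id`, `result`).
#' @param mutation_ids Optional extra mutation labels with no tested pair.
#' @return A [complementation_matrix()].
#' @export
read_matrix <- function(path, deficiencies = NULL, mutation_ids = NULL) {
  df <- read_tsv_rows(path, required = c("mutation_a", "mutation_b", "result"),
                      optional = "channel")
  def <- if (!is.null(deficiencies)) {
    read_tsv_rows(deficiencies,
                  required = c("mutation", "deficiency_id", "result"))
  }
  complementation_matrix(df, mutation_ids = mutation_ids,
                         deficiency_tests = def)
}

#' Write a complementation matrix to TSV
#'
#' @param matrix A [complementation_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "complementation_matrix"))
  p <- matrix$pairs
  chan <- ifelse(is.na(p$channel), "", p$channel)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("mutation_a\tmutation_b\tresult\tchannel",
               sprintf("%s\t%s\t%s\t%s", p$mutation_a, p$mutation_b,
                       p$result, chan)),
             con, sep = "\n")
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata`; with no argument,
#'   lists the available files. `table1_spectrum.tsv` is the allele spectrum
#'   of the published screen (45 mutations over 24 loci); the
#'   `ago1_synthetic_*` files encode the complex-complementation pattern
#'   reported for Ago1 as a constructed fixture.
#' @return A file path (or a vector of file names).
#' @export
mosaicsat_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "mosaicsat")))
  }
  path <- system.file("extdata", file, package = "mosaicsat")
  if (!nzchar(path)) abort_validation(sprintf("no packaged example file '%s'", file))
  path
}

#' Assemble a run report
#'
#' A report couples machine-readable results with the warnings raised while
#' computing them; inconsistency warnings (e.g. a printed lethal total that
#' contradicts arms x rate) are scientific output, not log noise, so they
#' travel with the numbers.
#'
#' @param subcommand Name of the analysis that produced the results.
#' @param results Named list of results (must be JSON-representable).
#' @param warnings Character vector of warning messages raised.
#' @param config Named list echoing the configuration used.
#' @return An object of class `mosaicsat_report`.
#' @export
new_report <- function(subcommand, results, warnings = character(),
                       config = list()) {
  structure(
    list(
      package = "mosaicsat",
      version = as.character(utils::packageVersion("mosaicsat")),
      subcommand = subcommand,
      config = config,
      results = results,
      warnings = as.character(warnings)
    ),
    class = "mosaicsat_report"
  )
}

#' Write a report as JSON and markdown
#'
#' @param report A [new_report()].
#' @param dir Output directory (created if needed). Writes
#'   `<subcommand>_report.json` and `<subcommand>_report.md`.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mosaicsat_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(report$subcommand, "_report.json"))
  md_path <- file.path(dir, paste0(report$subcommand, "_report.md"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  flat <- flatten_results(report$results)
  md <- c(
    sprintf("# mosaicsat %s report", report$subcommand),
    "",
    sprintf("Package version %s.", report$version),
    "",
    "| quantity | value |",
    "| --- | --- |",
    sprintf("| %s | %s |", names(flat), vapply(flat, format_cell, character(1)))
  )
  if (length(report$warnings)) {
    md <- c(md, "", "## Warnings", "", paste0("- ", report$warnings))
  }
  con <- file(md_path, open = "wb")
  writeLines(md, con, sep = "\n")
  close(con)
  invisible(c(json = json_path, md = md_path))
}

flatten_results <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_results(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

format_cell <- function(v) {
  if (is.numeric(v)) paste(format(v, digits = 10), collapse = ", ")
  else paste(as.character(v), collapse = ", ")
}

#' @export
print.mosaicsat_report <- function(x, ...) {
  cat(sprintf("mosaicsat %s report (version %s)\n", x$subcommand, x$version))
  flat <- flatten_results(x$results)
  for (nm in names(flat)) {
    cat(sprintf("  %s: %s\n", nm, format_cell(flat[[nm]])))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat(sprintf("    - %s\n", w))
  }
  invisible(x)
}

# Read a YAML config file into a named list (empty list for empty file).
read_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) list() else cfg
}
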