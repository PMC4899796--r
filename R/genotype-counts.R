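#' Case-control genotype counts for a biallelic marker
#'
#' Container for the observed 2x3 table of a case-control genetic association
#' study: genotype counts (aa, Aa, AA) for cases and for controls. The
#' coordinate convention throughout the package is that genotype index
#' `i` equals the number of copies of the `A` (second-listed) allele, so the
#' column order is always `aa` (0), `Aa` (1), `AA` (2). Margins (`r`, `s`,
#' `n_i`, `n`) are always recomputed from the six cells, never stored.
#'
#' @param cases Integer vector of length 3: case counts for aa, Aa, AA.
#' @param controls Integer vector of length 3: control counts for aa, Aa, AA.
#'
#' @return An object of class `genotype_counts`.
#'
#' @examples
#' # Lung-cancer case-control data for a Val762Ala polymorphism
#' gc <- genotype_counts(cases = c(307, 509, 184), controls = c(359, 522, 137))
#' gc
#' observed_pooled_freqs(gc)
#' @export
genotype_counts <- function(cases, controls) {
  cases <- check_count_vector(cases, "cases")
  controls <- check_count_vector(controls, "controls")
  structure(
    list(cases = cases, controls = controls),
    class = "genotype_counts"
  )
}

check_count_vector <- function(x, what) {
  if (length(x) != 3L || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric vector of length 3 (aa, Aa, AA).", what))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", what))
  if (any(x < 0)) {
    abort(sprintf("`%s` contains a negative count (%s).", what,
                  paste(x[x < 0], collapse = ", ")))
  }
  if (any(abs(x - round(x)) > 1e-8)) {
    abort(sprintf(
      "`%s` contains non-integer counts (%s); proportions are not accepted.",
      what, paste(x[abs(x - round(x)) > 1e-8], collapse = ", ")))
  }
  setNames(as.integer(round(x)), GENOTYPES)
}

#' @export
print.genotype_counts <- function(x, ...) {
  m <- rbind(Cases = x$cases, Controls = x$controls,
             Total = x$cases + x$controls)
  m <- cbind(m, Total = rowSums(m))
  cat("Case-control genotype counts (2x3)\n")
  print(m)
  invisible(x)
}

#' @export
as.data.frame.genotype_counts <- function(x, ...) {
  as.data.frame(tidy(x))
}

#' Tidy a genotype_counts object into one row per cell
#'
#' @param x A [genotype_counts()] object.
#' @param ... Unused.
#' @return A tibble with columns `status`, `genotype`, `count`.
#' @exportS3Method generics::tidy
#' @export
tidy.genotype_counts <- function(x, ...) {
  tibble::tibble(
    status = rep(c("case", "control"), each = 3L),
    genotype = rep(GENOTYPES, 2L),
    count = c(unname(x$cases), unname(x$controls))
  )
}

# Margins recomputed on demand.
gc_margins <- function(x) {
  r <- sum(x$cases); s <- sum(x$controls)
  list(r = r, s = s, n_i = x$cases + x$controls, n = r + s)
}

stop_if_empty_margin <- function(x) {
  m <- gc_margins(x)
  if (m$r < 1L) abort("no cases: at least one case is required.")
  if (m$s < 1L) abort("no controls: at least one control is required.")
  invisible(m)
}

#' Pooled genotype frequencies of the observed sample
#'
#' Combined-sample genotype proportions `n_i / n`, the observed analogue of
#' the model-implied pooled frequencies used by the trend-test variance.
#'
#' @param counts A [genotype_counts()] object.
#' @return Named numeric vector of length 3 summing to 1.
#' @export
observed_pooled_freqs <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  m <- gc_margins(counts)
  if (m$n == 0L) abort("empty table: total sample size is zero.")
  m$n_i / m$n
}

#' Tally subject-level records into genotype counts
#'
#' @param records A data frame with columns `status` (`"case"`/`"control"`)
#'   and `genotype` (integer 0, 1 or 2 = number of A alleles).
#' @return A [genotype_counts()] object.
#' @export
aggregate_subjects <- function(records) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  if (nrow(records) == 0L) abort("no subjects: the record set is empty.")
  need <- c("status", "genotype")
  if (!all(need %in% names(records))) {
    abort("`records` must have columns `status` and `genotype`.")
  }
  status <- normalize_status(records$status)
  geno <- records$genotype
  bad <- which(!(geno %in% c(0, 1, 2)))
  if (length(bad) > 0L) {
    abort(sprintf("invalid genotype code %s at record %d (must be 0, 1 or 2).",
                  deparse(geno[bad[1L]]), bad[1L]))
  }
  tab <- function(st) {
    vapply(0:2, function(g) sum(status == st & geno == g), numeric(1))
  }
  genotype_counts(cases = tab("case"), controls = tab("control"))
}

normalize_status <- function(status) {
  st <- tolower(trimws(as.character(status)))
  st <- sub("s$", "", st)
  bad <- which(!(st %in% c("case", "control")))
  if (length(bad) > 0L) {
    abort(sprintf("unknown status %s at record %d (expected case/control).",
                  deparse(as.character(status)[bad[1L]]), bad[1L]))
  }
  st
}

#' Expand genotype counts into one record per subject
#'
#' Inverse of [aggregate_subjects()].
#'
#' @param counts A [genotype_counts()] object.
#' @return A tibble with columns `status` and `genotype`.
#' @export
as_subject_records <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  tibble::tibble(
    status = rep(rep(c("case", "control"), each = 3L),
                 times = c(counts$cases, counts$controls)),
    genotype = rep(rep(0:2, 2L), times = c(counts$cases, counts$controls))
  )
}

#' Read a case-control genotype table from CSV/TSV
#'
#' Two layouts are accepted. `wide`: one row per status (`case`, `control`)
#' and one column per genotype, headers from `{aa, Aa, AA}`
#' (case-insensitive) or `{0, 1, 2}`, in any order. `long`: one subject per
#' row with columns `status` and `genotype`. The field separator (comma or
#' tab) is sniffed from the first line.
#'
#' @param source Path to a file, or a literal string containing the data.
#' @param layout `"wide"` or `"long"`.
#' @return A [genotype_counts()] object.
#' @export
read_genotype_table <- function(source, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  txt <- if (length(source) == 1L && !grepl("[\n,\t]", source)) {
    if (!file.exists(source)) abort(sprintf("file not found: %s", source))
    readLines(source, warn = FALSE)
  } else {
    strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  }
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0L) abort("no subjects: input is empty.")
  sep <- if (grepl("\t", txt[1L])) "\t" else ","
  df <- read.table(text = txt, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, strip.white = TRUE,
                   fileEncoding = "UTF-8")
  if (layout == "long") {
    names(df) <- tolower(names(df))
    return(aggregate_subjects(df))
  }
  parse_wide_table(df)
}

parse_wide_table <- function(df) {
  if (nrow(df) < 2L) abort("wide layout needs a `case` row and a `control` row.")
  label_col <- 1L
  labels <- tolower(trimws(as.character(df[[label_col]])))
  labels <- sub("s$", "", labels)
  i_case <- match("case", labels)
  i_ctrl <- match("control", labels)
  if (is.na(i_case)) abort("missing row: no row labelled `case(s)`.")
  if (is.na(i_ctrl)) abort("missing row: no row labelled `control(s)`.")
  geno_idx <- match_genotype_headers(names(df)[-label_col])
  cols <- setdiff(seq_along(df), label_col)[order(geno_idx)]
  read_row <- function(i, what) {
    v <- suppressWarnings(as.numeric(unlist(df[i, cols])))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      abort(sprintf("cell (%s, %s) is not a number.", what, GENOTYPES[j]))
    }
    v
  }
  genotype_counts(cases = read_row(i_case, "case"),
                  controls = read_row(i_ctrl, "control"))
}

match_genotype_headers <- function(headers) {
  h <- trimws(headers)
  # Accept {aa, Aa, AA} by A-allele copy count, or {0,1,2}, or X0/X1/X2 as
  # produced by read.table on numeric headers.
  code <- function(tok) {
    t0 <- tolower(tok)
    if (t0 %in% c("aa")) {
      # ambiguous in lower case: distinguish by capitalization of the original
      n_upper <- sum(strsplit(tok, "")[[1L]] %in% LETTERS)
      return(n_upper)
    }
    if (t0 %in% c("0", "x0")) return(0L)
    if (t0 %in% c("1", "x1")) return(1L)
    if (t0 %in% c("2", "x2")) return(2L)
    NA_integer_
  }
  idx <- vapply(h, code, integer(1))
  if (anyNA(idx) || !setequal(idx, 0:2)) {
    abort(sprintf(
      "missing column: genotype headers must be {aa, Aa, AA} or {0, 1, 2}; got %s.",
      paste(headers, collapse = ", ")))
  }
  idx
}

#' Write a genotype table to CSV
#'
#' @param counts A [genotype_counts()] object.
#' @param file Output path.
#' @param layout `"wide"` (2 rows x 3 genotype columns) or `"long"`
#'   (one subject per row).
#' @return `file`, invisibly.
#' @export
write_genotype_table <- function(counts, file, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(counts, "genotype_counts"))
  if (layout == "wide") {
    df <- data.frame(status = c("case", "control"),
                     rbind(counts$cases, counts$controls),
                     check.names = FALSE)
    names(df) <- c("status", GENOTYPES)
  } else {
    df <- as.data.frame(as_subject_records(counts))
  }
  write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(file)
}

#' Serialize genotype counts to JSON
#'
#' @param counts A [genotype_counts()] object.
#' @return A JSON string with cases, controls and recomputed margins.
#' @export
genotype_counts_json <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  m <- gc_margins(counts)
  jsonlite::toJSON(list(
    genotypes = GENOTYPES,
    cases = unname(counts$cases),
    controls = unname(counts$controls),
    totals = unname(m$n_i),
    n_cases = m$r, n_controls = m$s, n = m$n
  ), auto_unbox = TRUE)
}
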