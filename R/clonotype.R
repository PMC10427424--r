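#' Construct a clonotype table
#'
#' A `clonotype_table` is a data frame of TCR-beta clonotype records for a
#' single sample (one patient, compartment and timepoint), with columns
#' `count`, `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`, `j`. Frequencies are
#' recomputed from counts unless supplied; records with identical clonotype
#' keys are merged by summing counts.
#'
#' @param records data frame with at least `count` and `cdr3aa`; `cdr3nt`,
#'   `v`, `d`, `j` default to `"."` (unresolved) when absent.
#' @param patient patient identifier.
#' @param compartment `"tumor"` or `"blood"`.
#' @param timepoint one of `"baseline"`, `"W3"`, `"W6"`, `"post_surgery"`.
#' @param key clonotype identity key: `"aa_vj"` (CDR3 amino acids plus V and
#'   J segment, the default) or `"nt"` (CDR3 nucleotide sequence).
#' @return A `clonotype_table` data frame with metadata attributes.
#' @examples
#' tab <- clonotype_table(data.frame(count = c(2, 1, 1),
#'                                   cdr3aa = c("CASSF", "CASRW", "CASTW")))
#' clonality(tab)
#' @export
clonotype_table <- function(records, patient = NA_character_,
                            compartment = NA_character_,
                            timepoint = NA_character_,
                            key = c("aa_vj", "nt")) {
  key <- match.arg(key)
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  for (col in c("count", "cdr3aa")) {
    if (!col %in% names(records))
      stop(sprintf("clonotype records lack required column '%s'", col))
  }
  for (col in c("cdr3nt", "v", "d", "j")) {
    if (!col %in% names(records)) records[[col]] <- "."
  }
  if (any(records$count != round(records$count)) || any(records$count < 1))
    stop("'count' must contain positive integers")
  if (!is.na(compartment) && !compartment %in% c("tumor", "blood"))
    stop("compartment must be 'tumor' or 'blood'")
  if (!is.na(timepoint) &&
      !timepoint %in% c("baseline", "W3", "W6", "post_surgery"))
    stop("timepoint must be one of baseline, W3, W6, post_surgery")

  records$count <- as.numeric(records$count)
  k <- clone_key_of(records, key)
  if (anyDuplicated(k)) {
    count <- tapply(records$count, k, sum)
    first <- records[!duplicated(k), , drop = FALSE]
    first <- first[order(clone_key_of(first, key)), , drop = FALSE]
    first$count <- as.numeric(count[clone_key_of(first, key)])
    records <- first
  }
  records$freq <- records$count / sum(records$count)
  rownames(records) <- NULL
  out <- records[, c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")]
  structure(out,
            class = c("clonotype_table", "data.frame"),
            patient = patient, compartment = compartment,
            timepoint = timepoint, key = key)
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("Clonotype table: %d clonotypes, %d templates\n",
              nrow(x), round(sum(x$count))))
  cat(sprintf("  patient=%s compartment=%s timepoint=%s key=%s\n",
              attr(x, "patient"), attr(x, "compartment"),
              attr(x, "timepoint"), attr(x, "key")))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

clone_key_of <- function(records, key) {
  if (key == "nt") records$cdr3nt
  else paste(records$cdr3aa, records$v, records$j, sep = "|")
}

#' Clonotype identity keys of a table
#'
#' @param table a `clonotype_table`.
#' @return character vector of keys, one per record, using the table's key
#'   definition (`"aa_vj"` or `"nt"`).
#' @export
clone_keys <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  clone_key_of(table, attr(table, "key"))
}

#' Read a VDJtools-style clonotype TSV
#'
#' Expects a header with columns `count`, `freq` (optional), `cdr3nt`
#' (optional), `cdr3aa`, `v`, `d`, `j` (case-insensitive; `frequency`,
#' `#count` and similar variants are accepted). Frequencies are recomputed
#' from counts.
#'
#' @param path file path.
#' @inheritParams clonotype_table
#' @return a `clonotype_table`.
#' @export
read_clonotype_table <- function(path, patient = NA_character_,
                                 compartment = NA_character_,
                                 timepoint = NA_character_,
                                 key = c("aa_vj", "nt")) {
  key <- match.arg(key)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  nm <- tolower(sub("^#", "", names(df)))
  nm[nm == "frequency"] <- "freq"
  names(df) <- nm
  for (col in c("count", "cdr3aa", "v", "j")) {
    if (!col %in% nm)
      stop(sprintf("clonotype file '%s' is missing required column '%s'",
                   path, col))
  }
  if (any(is.na(suppressWarnings(as.numeric(df$count)))) ||
      any(as.numeric(df$count) != round(as.numeric(df$count))))
    stop("column 'count' must contain integers")
  clonotype_table(df, patient = patient, compartment = compartment,
                  timepoint = timepoint, key = key)
}

#' Write a clonotype table as VDJtools-style TSV
#'
#' @param table a `clonotype_table`.
#' @param path output file path.
#' @return `path`, invisibly. Round-trips with [read_clonotype_table()].
#' @export
write_clonotype_table <- function(table, path) {
  stopifnot(inherits(table, "clonotype_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Productive-CDR3 predicate
#'
#' A CDR3 amino-acid sequence is productive when it contains no stop (`*`)
#' or frameshift (`_`) symbol, is at least 5 residues long, starts with `C`
#' and ends with `F` or `W`.
#'
#' @param cdr3aa character vector of CDR3 amino-acid sequences.
#' @return logical vector.
#' @export
is_productive_cdr3 <- function(cdr3aa) {
  !grepl("[*_]", cdr3aa, fixed = FALSE) &
    nchar(cdr3aa) >= 5 &
    substr(cdr3aa, 1, 1) == "C" &
    substr(cdr3aa, nchar(cdr3aa), nchar(cdr3aa)) %in% c("F", "W")
}

#' Filter a clonotype table to productive CDR3s
#'
#' Retains exactly the records whose amino-acid CDR3 passes
#' [is_productive_cdr3()] and re-normalizes frequencies over the retained
#' records. An empty result is returned with a warning, not an error.
#'
#' @param table a `clonotype_table`.
#' @return the filtered `clonotype_table`.
#' @export
filter_productive <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  keep <- is_productive_cdr3(table$cdr3aa)
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no productive clonotypes remain after filtering")
    out$freq <- numeric(0)
  } else {
    out$freq <- out$count / sum(out$count)
  }
  rownames(out) <- NULL
  attributes_keep(out, table)
}

attributes_keep <- function(out, template) {
  attr(out, "patient") <- attr(template, "patient")
  attr(out, "compartment") <- attr(template, "compartment")
  attr(out, "timepoint") <- attr(template, "timepoint")
  attr(out, "key") <- attr(template, "key")
  class(out) <- c("clonotype_table", "data.frame")
  out
}

#' TCR richness
#'
#' Richness is the number of unique clonotypes in the repertoire (duplicate
#' key rows are merged at construction time).
#'
#' @param table a `clonotype_table`.
#' @return integer count of unique clonotype keys.
#' @export
richness <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  length(unique(clone_keys(table)))
}

#' Productive clonality
#'
#' Clonality is `1 - H / ln(R)` where `H` is the Shannon entropy of the
#' clonotype frequencies (natural log) and `R` the richness. A value of 0
#' is the most diverse repertoire (every template a distinct clonotype); 1
#' is a monoclonal population. A repertoire of richness 1 returns 1 by
#' convention (the limit of a maximally dominated repertoire).
#'
#' @param table a `clonotype_table` (normally productive-filtered first).
#' @return clonality in `[0, 1]`.
#' @export
clonality <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0) stop("clonality is undefined for an empty table")
  r <- richness(table)
  if (r == 1) return(1)
  f <- table$freq / sum(table$freq)
  h <- -sum(f * log(f))
  1 - h / log(r)
}
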