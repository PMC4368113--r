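## Genotype file I/O: GenePop (2- or 3-digit allele coding) and a
## delimiter-separated table dialect carrying metadata.

#' Read genotypes from file
#'
#' Reads a [GenotypeTable-class] from either GenePop format or the
#' package's tab-separated table dialect.
#'
#' GenePop files: first line is a title, then locus names (one per line,
#' or a single comma-separated line), then one or more \code{Pop}
#' sections with lines \code{"id , 0102 0304 ..."}. Both 2-digit and
#' 3-digit allele codings are accepted (detected from token width);
#' allele code 0 means missing. GenePop carries no sex/length/cohort
#' metadata, so those are filled from the \code{cohort} argument and
#' unknown sex.
#'
#' Table files: tab-separated with header columns \code{id}, \code{sex},
#' \code{fork_length_mm}, \code{cohort}, then two columns per locus named
#' \code{<locus>_a} and \code{<locus>_b}; 0 codes a missing allele.
#'
#' @param path file path.
#' @param format \code{"genepop"} or \code{"table"}.
#' @param cohort cohort label used for GenePop input (default
#'   \code{"ADULT"}).
#' @return a validated [GenotypeTable-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("genepop", "table"),
                          cohort = "ADULT") {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  switch(format,
         genepop = .readGenepop(path, cohort = cohort),
         table = .readTableDialect(path))
}

#' Write genotypes to file
#'
#' Writes a [GenotypeTable-class] to GenePop (3-digit coding, one
#' \code{Pop} per cohort; metadata other than ids is not representable)
#' or to the table dialect (full metadata). Reading the written file back
#' recovers the ids, loci and genotypes exactly.
#'
#' @param table a [GenotypeTable-class]; must contain at least one
#'   individual.
#' @param path output file path.
#' @param format \code{"genepop"} or \code{"table"}.
#' @return the path, invisibly.
#' @export
writeGenotypes <- function(table, path, format = c("genepop", "table")) {
  format <- match.arg(format)
  if (nIndividuals(table) == 0L) .stopf("no individuals to write")
  switch(format,
         genepop = .writeGenepop(table, path),
         table = .writeTableDialect(table, path))
  invisible(path)
}

.readGenepop <- function(path, cohort = "ADULT") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) .stopf("not a GenePop file: %s", path)
  body <- lines[-1L]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) .stopf("no 'Pop' line found in %s", path)
  locus_lines <- body[seq_len(pop_idx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  if (anyDuplicated(loci)) .stopf("duplicate locus name in %s", path)
  n_loci <- length(loci)
  ind_lines <- body[-seq_len(pop_idx[1L])]
  ind_lines <- ind_lines[!grepl("^\\s*pop\\s*$", ind_lines,
                                ignore.case = TRUE)]
  ind_lines <- ind_lines[trimws(ind_lines) != ""]
  n <- length(ind_lines)
  if (n == 0L) .stopf("no individuals in %s", path)
  ids <- character(n)
  a <- matrix(NA_integer_, n, n_loci)
  b <- matrix(NA_integer_, n, n_loci)
  for (k in seq_len(n)) {
    parts <- strsplit(ind_lines[k], ",")[[1L]]
    if (length(parts) < 2L)
      .stopf("line %d: expected 'id , genotypes'", k)
    ids[k] <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = " ")),
                     "\\s+")[[1L]]
    if (length(toks) != n_loci)
      .stopf("line %d: %d genotype fields, expected %d (ragged input)",
             k, length(toks), n_loci)
    w <- nchar(toks)
    if (!all(w %in% c(4L, 6L)))
      .stopf("line %d: genotype fields must be 4 or 6 digits", k)
    half <- w %/% 2L
    a[k, ] <- as.integer(substr(toks, 1L, half))
    b[k, ] <- as.integer(substr(toks, half + 1L, w))
  }
  if (anyDuplicated(ids))
    .stopf("duplicate id: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a[a == MISSING_CODE] <- NA_integer_
  b[b == MISSING_CODE] <- NA_integer_
  dimnames(a) <- dimnames(b) <- list(ids, loci)
  GenotypeTable(a, b, cohort = cohort)
}

.writeGenepop <- function(table, path) {
  am <- alleleMatrices(table)
  if (any(!is.na(am$a) & (am$a > 999L | am$b > 999L)))
    .stopf("allele > 999 cannot be encoded with 3-digit GenePop coding")
  a <- am$a
  b <- am$b
  a[is.na(a)] <- MISSING_CODE
  b[is.na(b)] <- MISSING_CODE
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("polyParent genotype export", con)
  writeLines(lociNames(table), con)
  coh <- cohortOf(table)
  for (grp in unique(coh)) {
    writeLines("Pop", con)
    for (i in which(coh == grp)) {
      genos <- sprintf("%03d%03d", a[i, ], b[i, ])
      writeLines(paste0(individualIds(table)[i], " , ",
                        paste(genos, collapse = " ")), con)
    }
  }
}

.readTableDialect <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = c(id = "character",
                                         sex = "character",
                                         fork_length_mm = "numeric",
                                         cohort = "character"))
  need <- c("id", "sex", "fork_length_mm", "cohort")
  if (!all(need %in% names(df)))
    .stopf("table file must have columns %s", paste(need, collapse = ", "))
  locus_cols <- setdiff(names(df), need)
  a_cols <- grep("_a$", locus_cols, value = TRUE)
  loci <- sub("_a$", "", a_cols)
  b_cols <- paste0(loci, "_b")
  if (!all(b_cols %in% locus_cols))
    .stopf("every locus needs both _a and _b columns")
  ids <- as.character(df$id)
  if (anyDuplicated(ids))
    .stopf("duplicate id: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a <- as.matrix(df[, a_cols, drop = FALSE])
  b <- as.matrix(df[, b_cols, drop = FALSE])
  storage.mode(a) <- "integer"
  storage.mode(b) <- "integer"
  a[a == MISSING_CODE] <- NA_integer_
  b[b == MISSING_CODE] <- NA_integer_
  dimnames(a) <- dimnames(b) <- list(ids, loci)
  GenotypeTable(a, b, sex = as.character(df$sex),
                forkLength = as.numeric(df$fork_length_mm),
                cohort = as.character(df$cohort))
}

.writeTableDialect <- function(table, path) {
  am <- alleleMatrices(table)
  a <- am$a
  b <- am$b
  a[is.na(a)] <- MISSING_CODE
  b[is.na(b)] <- MISSING_CODE
  loci <- lociNames(table)
  out <- data.frame(id = individualIds(table),
                    sex = table@sex,
                    fork_length_mm = table@forkLength,
                    cohort = table@cohort,
                    stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    out[[paste0(loci[j], "_a")]] <- a[, j]
    out[[paste0(loci[j], "_b")]] <- b[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write the per-locus summary table
#'
#' Writes the output of [locusSummaries()] as tab-separated text with
#' columns Locus, Na, Ho, He, PIC, hwe_p, hwe_p_adj (the column layout of
#' a standard genetic-diversity report).
#'
#' @param summaries data.frame from [locusSummaries()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLocusSummaries <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
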