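#' File input/output
#'
#' All tables are plain text, UTF-8, with `#` comment lines.  Pedigree and
#' phenotype files are delimited (comma or whitespace) with a header row;
#' genotype files are either fixed-format (id plus a contiguous string of
#' gene contents) or delimited, with gene contents coded 0/1/2 and missing
#' values coded 5.
#'
#' @name data_io
NULL

.read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    blank.lines.skip = TRUE)
}

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  sep <- if (length(first) && grepl(",", first[1])) "," else ""
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, blank.lines.skip = TRUE)
}

#' Read a pedigree file
#'
#' @param path delimited file with columns `id`, `sire`, `dam` and
#'   optionally `birth_year`, `sex`, `breed_code`; unknown parents coded
#'   `0` (or empty).
#' @param mf_rules optional breed-code to metafounder-label map; when given,
#'   unknown parent slots are replaced by metafounder pseudo-parents.
#' @param default_group see [add_metafounders()].
#' @return a [ped_table].
#' @export
read_pedigree <- function(path, mf_rules = NULL, default_group = "U") {
  df <- .read_delim_auto(path)
  names(df) <- tolower(names(df))
  if ("animal" %in% names(df) && !"id" %in% names(df)) {
    names(df)[names(df) == "animal"] <- "id"
  }
  as_ped_table(df, mf_rules = mf_rules, default_group = default_group)
}

#' Write a pedigree file
#' @param ped a [ped_table]; metafounder rows are omitted and parents that
#'   point at them are written as `0`.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "ped_table"))
  df <- as.data.frame(ped)
  mf <- df$id[df$is_metafounder]
  df <- df[!df$is_metafounder, c("id", "sire", "dam", "birth_year", "sex", "breed_code")]
  df$sire[is.na(df$sire) | df$sire %in% mf] <- "0"
  df$dam[is.na(df$dam) | df$dam %in% mf] <- "0"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Gene-content (genotype) matrices
#'
#' A `geno_matrix` holds animals x markers gene contents as an integer
#' matrix with `NA` for missing entries, plus per-marker allele frequencies
#' and call rates computed on the non-missing entries.
#'
#' @param M integer matrix (animals x markers), entries 0/1/2 or `NA`.
#' @param ids animal identifiers (row names).
#' @param markers marker identifiers (column names); generated if `NULL`.
#' @return object of class `geno_matrix` with fields `M`, `ids`, `markers`,
#'   `p` (frequency of the counted allele), `marker_call_rate`,
#'   `animal_call_rate`.
#' @export
geno_matrix <- function(M, ids = rownames(M), markers = colnames(M)) {
  M <- as.matrix(M)
  storage.mode(M) <- "integer"
  bad <- !is.na(M) & !(M %in% 0:2)
  if (any(bad)) stop("gene contents must be 0, 1 or 2 (missing = NA)")
  if (is.null(ids)) stop("animal ids required")
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(M)))
  dimnames(M) <- list(ids, markers)
  obs <- !is.na(M)
  structure(list(
    M = M, ids = as.character(ids), markers = as.character(markers),
    p = colSums(M, na.rm = TRUE) / (2 * pmax(colSums(obs), 1L)),
    marker_call_rate = colMeans(obs),
    animal_call_rate = rowMeans(obs)
  ), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d animals x %d markers, %.2f%% missing\n",
              nrow(x$M), ncol(x$M), 100 * mean(is.na(x$M))))
  invisible(x)
}

#' Read a genotype file
#'
#' Accepts the fixed format `id 012052...` (one contiguous string of gene
#' contents per animal, missing coded 5) or a delimited variant with one
#' column per marker.  No header row.
#'
#' @param path genotype file.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty genotype file")
  parts <- strsplit(lines, "[ \t]+")
  ids <- vapply(parts, `[[`, "", 1L)
  rows <- lapply(parts, function(p) {
    g <- p[-1]
    if (length(g) == 1L) g <- strsplit(g, "")[[1]]
    g
  })
  len <- lengths(rows)
  if (length(unique(len)) != 1L) {
    stop("genotype rows have unequal length (first mismatch: animal ",
         ids[which(len != len[1])[1]], ")")
  }
  flat <- unlist(rows, use.names = FALSE)
  if (!all(flat %in% c("0", "1", "2", "5"))) {
    stop("genotype symbols outside {0,1,2,5}: ",
         paste(utils::head(setdiff(unique(flat), c("0", "1", "2", "5")), 3), collapse = ", "))
  }
  M <- matrix(as.integer(flat), nrow = length(rows), byrow = TRUE)
  M[M == 5L] <- NA_integer_
  geno_matrix(M, ids = ids)
}

#' Write a genotype file (fixed format, missing coded 5)
#' @param G a [geno_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(G, path) {
  M <- G$M
  M[is.na(M)] <- 5L
  txt <- paste(G$ids, apply(M, 1L, paste, collapse = ""))
  writeLines(txt, path)
  invisible(path)
}

#' Read a phenotype file
#'
#' @param path CSV with columns `animal`, `trait`, `cg` (contemporary
#'   group), `age`, `value`, and optionally `zebu`, `het`, `recloss`
#'   (breed-composition covariates in `[0, 1]`).
#' @param ped a [ped_table] used to validate animal ids.
#' @return data frame of class `pheno_table`; one row per record, with a
#'   `n_records` per-animal count column attached.
#' @export
read_phenotypes <- function(path, ped) {
  df <- .read_delim_auto(path)
  names(df) <- tolower(names(df))
  if ("id" %in% names(df) && !"animal" %in% names(df)) {
    names(df)[names(df) == "id"] <- "animal"
  }
  as_pheno_table(df, ped)
}

#' Validate a phenotype data frame against a pedigree
#' @inheritParams read_phenotypes
#' @param df data frame (see [read_phenotypes()] for columns).
#' @export
as_pheno_table <- function(df, ped) {
  need <- c("animal", "trait", "cg", "value")
  if (nrow(df) == 0) {
    warning("empty phenotype table")
    out <- data.frame(animal = character(0), trait = character(0),
                      cg = character(0), age = numeric(0), value = numeric(0))
    class(out) <- c("pheno_table", "data.frame")
    return(out)
  }
  if (!all(need %in% names(df))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  df$animal <- as.character(df$animal)
  df$trait <- as.character(df$trait)
  df$cg <- as.character(df$cg)
  df$value <- as.numeric(df$value)
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  unknown <- setdiff(df$animal, ped$id)
  if (length(unknown) > 0) {
    stop("phenotyped animals absent from pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  tt <- unique(df[c("animal", "trait")])
  dup <- tt$animal[duplicated(tt$animal)]
  if (length(dup) > 0) {
    stop("animals with records under two trait codes: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  for (cv in intersect(c("zebu", "het", "recloss"), names(df))) {
    v <- as.numeric(df[[cv]])
    if (any(v < -1e-8 | v > 1 + 1e-8, na.rm = TRUE)) {
      stop("covariate ", cv, " outside [0, 1]")
    }
    df[[cv]] <- v
  }
  cnt <- table(df$animal)
  df$n_records <- as.integer(cnt[df$animal])
  rownames(df) <- NULL
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Write a phenotype file
#' @param phe a `pheno_table`.
#' @param path output CSV.
#' @export
write_phenotypes <- function(phe, path) {
  df <- as.data.frame(phe)
  df$n_records <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a metafounder relationship matrix (labelled square CSV)
#' @param path CSV file with a header of metafounder labels and one labelled
#'   row per metafounder.
#' @return a [metafounder_set()].
#' @export
read_gamma <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE, comment.char = "#")
  metafounder_set(rownames(df), as.matrix(df))
}

#' @rdname read_gamma
#' @param mfs a [metafounder_set()].
#' @export
write_gamma <- function(mfs, path) {
  g <- mfs$gamma
  dimnames(g) <- list(mfs$labels, mfs$labels)
  utils::write.csv(as.data.frame(g), path, quote = FALSE)
  invisible(path)
}
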