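#' Pedigree tables
#'
#' A `ped_table` is a data frame with one row per individual and columns
#' `id`, `sire`, `dam` (character; `NA` for an unknown parent), `birth_year`
#' (integer), `sex` (`"M"`, `"F"` or `NA`), `founder_group` (metafounder
#' label for individuals with at least one unknown parent slot, otherwise
#' `NA`) and `is_metafounder` (logical).  Rows are stored in a valid
#' processing order: every parent precedes its offspring, and metafounder
#' pseudo-individuals (if present) come first.  The attribute
#' `metafounder_labels` holds the ordered labels of the metafounder groups.
#'
#' @name ped_table
NULL

#' Build a validated, ordered pedigree table
#'
#' Validates a raw pedigree data frame, detects cycles and undefined
#' parents, and reorders rows so that parents always precede offspring.
#' Ties are broken by birth year and then by input order.
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `birth_year`, `sex`, `breed_code`.  Unknown parents may be coded `NA`,
#'   `""` or `"0"`.
#' @param mf_rules optional named character vector mapping breed-of-origin
#'   codes to metafounder labels.  When supplied, every unknown parent slot
#'   is replaced by a metafounder pseudo-parent (see [add_metafounders()]).
#' @param default_group metafounder label used for individuals whose breed
#'   code has no entry in `mf_rules` (default `"U"`, the unknown group).
#'   Set to `NULL` to make unmatched codes an error.
#' @return a [ped_table].
#' @export
as_ped_table <- function(df, mf_rules = NULL, default_group = "U") {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree must have columns id, sire, dam")
  }
  id   <- as.character(df$id)
  sire <- .clean_parent(df$sire)
  dam  <- .clean_parent(df$dam)
  if (anyDuplicated(id)) {
    stop("duplicated animal ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  undef <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(undef) > 0) {
    stop("parent id referenced but never defined: ", paste(undef, collapse = ", "))
  }
  ped <- data.frame(
    id = id, sire = sire, dam = dam,
    birth_year = if ("birth_year" %in% names(df)) as.integer(df$birth_year) else NA_integer_,
    sex = if ("sex" %in% names(df)) as.character(df$sex) else NA_character_,
    breed_code = if ("breed_code" %in% names(df)) as.character(df$breed_code) else NA_character_,
    founder_group = NA_character_,
    is_metafounder = FALSE,
    stringsAsFactors = FALSE
  )
  ped <- .ped_sort(ped)
  attr(ped, "metafounder_labels") <- character(0)
  class(ped) <- c("ped_table", "data.frame")
  if (!is.null(mf_rules)) {
    ped <- add_metafounders(ped, mf_rules, default_group = default_group)
  }
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Topological sort by parent-depth, then birth year, then input order.
# Cycle detection: depths must stabilise within n sweeps.
.ped_sort <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  depth <- rep.int(0L, n)
  for (sweep in seq_len(n + 1L)) {
    pd <- pmax(ifelse(is.na(si), 0L, depth[si] + 1L),
               ifelse(is.na(di), 0L, depth[di] + 1L))
    if (all(pd == depth)) break
    depth <- pd
    if (sweep == n + 1L) stop(.describe_cycle(ped, si, di))
  }
  if (any(depth > n)) stop(.describe_cycle(ped, si, di))
  by <- ped$birth_year
  by[is.na(by)] <- -.Machine$integer.max
  ord <- order(depth, by, seq_len(n))
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  ped
}

.describe_cycle <- function(ped, si, di) {
  # walk parent pointers until a repeat gives the offending loop
  n <- nrow(ped)
  for (start in seq_len(n)) {
    path <- integer(0)
    cur <- start
    while (!is.na(cur)) {
      if (cur %in% path) {
        loop <- ped$id[path[which(path == cur)[1]:length(path)]]
        return(paste0("pedigree cycle detected: ",
                      paste(c(loop, loop[1]), collapse = " -> ")))
      }
      path <- c(path, cur)
      cur <- if (!is.na(si[cur])) si[cur] else di[cur]
      if (length(path) > n) break
    }
  }
  "pedigree cycle detected"
}

#' Replace unknown parents by metafounder pseudo-parents
#'
#' Every missing parent slot is pointed at a metafounder pseudo-individual
#' chosen from the animal's breed-of-origin code through `mf_rules`.  An
#' animal with exactly one known parent receives a metafounder only for the
#' missing slot.  Pseudo-individuals (`MF_<label>`) are prepended to the
#' pedigree, flagged `is_metafounder`, and recorded in the
#' `metafounder_labels` attribute.
#'
#' @param ped a [ped_table] without metafounders.
#' @param mf_rules named character vector, breed code -> metafounder label.
#' @param default_group label for unmatched or missing breed codes
#'   (`NULL` to error instead).
#' @return a [ped_table] including metafounder rows.
#' @export
add_metafounders <- function(ped, mf_rules, default_group = "U") {
  stopifnot(inherits(ped, "ped_table"))
  if (any(ped$is_metafounder)) stop("pedigree already contains metafounders")
  miss_s <- is.na(ped$sire)
  miss_d <- is.na(ped$dam)
  needs <- miss_s | miss_d
  grp <- rep(NA_character_, nrow(ped))
  code <- ped$breed_code
  hit <- !is.na(code) & code %in% names(mf_rules)
  grp[hit] <- unname(mf_rules[code[hit]])
  if (any(needs & !hit)) {
    if (is.null(default_group)) {
      bad <- ped$id[needs & !hit]
      stop("no metafounder rule and no default group for: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    grp[needs & !hit] <- default_group
  }
  labels <- unique(c(unname(mf_rules), if (any(needs & !hit)) default_group))
  labels <- intersect(labels, grp[needs])     # keep only groups actually used
  mf_ids <- paste0("MF_", labels)
  ped$founder_group[needs] <- grp[needs]
  ped$sire[miss_s] <- paste0("MF_", grp[miss_s])
  ped$dam[miss_d]  <- paste0("MF_", grp[miss_d])
  mf_rows <- data.frame(
    id = mf_ids, sire = NA_character_, dam = NA_character_,
    birth_year = NA_integer_, sex = NA_character_,
    breed_code = NA_character_, founder_group = labels,
    is_metafounder = TRUE, stringsAsFactors = FALSE
  )
  out <- rbind(mf_rows, as.data.frame(ped)[names(mf_rows)])
  rownames(out) <- NULL
  attr(out, "metafounder_labels") <- labels
  class(out) <- c("ped_table", "data.frame")
  out
}

#' @export
print.ped_table <- function(x, ...) {
  labs <- metafounder_labels(x)
  cat(sprintf("ped_table: %d individuals (%d metafounders%s)\n",
              nrow(x), sum(x$is_metafounder),
              if (length(labs)) paste0(": ", paste(labs, collapse = ", ")) else ""))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Metafounder labels of a pedigree
#' @param ped a [ped_table].
#' @return character vector of labels (possibly empty).
#' @export
metafounder_labels <- function(ped) {
  labs <- attr(ped, "metafounder_labels")
  if (is.null(labs)) character(0) else labs
}

# parent row indices (NA for none); pedigree assumed ordered
.ped_idx <- function(ped) {
  list(si = match(ped$sire, ped$id), di = match(ped$dam, ped$id))
}
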