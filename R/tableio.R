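#' OTU count table with per-sample role flags
#'
#' The central container of the pipeline: a feature-by-sample matrix of
#' non-negative integer read counts (features as rows, samples as columns,
#' the QIIME-classic orientation), plus a role flag per sample separating
#' biological samples from spiked no-template extraction controls (NTCs)
#' and replicate library preparations.
#'
#' @param counts numeric matrix, features x samples, non-negative integers.
#'   Must carry unique rownames (feature IDs) and colnames (sample IDs).
#' @param roles character vector, one of `"biological"`, `"ntc_spiked"`,
#'   `"replicate"` per sample. Defaults to all biological. May be named by
#'   sample ID or positional.
#' @param replicate_of character vector naming, for samples with role
#'   `"replicate"`, the sample they duplicate; `NA` elsewhere.
#'
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `roles` and `replicate_of`.
#' @export
count_table <- function(counts, roles = NULL, replicate_of = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | !is_wholenumber(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  counts <- round(counts)

  n <- ncol(counts)
  if (is.null(roles)) roles <- rep("biological", n)
  if (!is.null(names(roles))) roles <- roles[colnames(counts)]
  roles <- as.character(roles)
  if (length(roles) != n) stop("roles must name every sample")
  ok <- roles %in% c("biological", "ntc_spiked", "replicate")
  if (!all(ok)) stop("unknown sample role: ", paste(unique(roles[!ok]), collapse = ", "))
  names(roles) <- colnames(counts)

  if (is.null(replicate_of)) replicate_of <- rep(NA_character_, n)
  if (!is.null(names(replicate_of))) replicate_of <- replicate_of[colnames(counts)]
  replicate_of <- as.character(replicate_of)
  names(replicate_of) <- colnames(counts)

  structure(list(counts = counts, roles = roles, replicate_of = replicate_of),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (%d biological, %d spiked-NTC, %d replicate)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$roles == "biological"), sum(x$roles == "ntc_spiked"),
              sum(x$roles == "replicate")))
  cat(sprintf("  read depth: median %s, range %s-%s\n",
              format(stats::median(colSums(x$counts))),
              format(min(colSums(x$counts))), format(max(colSums(x$counts)))))
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname count_table
#' @export
sample_depths <- function(x) colSums(x$counts)

#' Subset a count table to a set of samples, keeping role flags in step
#' @param x a `count_table`.
#' @param samples character vector of sample IDs (or logical/integer index).
#' @return a `count_table` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  count_table(x$counts[, samples, drop = FALSE],
              roles = x$roles[samples],
              replicate_of = x$replicate_of[samples])
}

#' @rdname subset_samples
#' @export
biological_samples <- function(x) sample_ids(x)[x$roles == "biological"]

taxonomy_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
rank_prefixes  <- c(kingdom = "k", phylum = "p", class = "c",
                    order = "o", family = "f", genus = "g")

#' Read an OTU count table from tab-separated text
#'
#' First column holds feature IDs (an optional leading `#OTU ID` header token
#' is accepted), the header row holds sample IDs, cells hold non-negative
#' integer read counts. Sample roles can be supplied through a metadata file
#' whose reserved `role` column flags spiked NTCs and replicates; without it
#' every sample is treated as biological.
#'
#' @param path path to the tab-separated count file.
#' @param roles optional path to a metadata TSV (see [read_metadata()]) whose
#'   `role` (and optional `replicate_of`) columns set per-sample flags.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, roles = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("count table needs a header row and >=1 feature row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (grepl("^#", header[1])) header <- header  # "#OTU ID" token allowed
  sample_names <- header[-1]
  if (anyDuplicated(sample_names))
    stop("duplicated sample header: ",
         paste(unique(sample_names[duplicated(sample_names)]), collapse = ", "))
  body <- fields[-1]
  ncols <- lengths(body)
  if (any(ncols != length(header)))
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 which(ncols != length(header))[1] + 1L, length(header),
                 ncols[ncols != length(header)][1]))
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(length(sample_names)))
  vals <- matrix(vals, nrow = length(sample_names))  # samples x features
  m <- t(vals)
  dimnames(m) <- list(ids, sample_names)
  bad <- which(is.na(m) | m < 0 | !is_wholenumber(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at feature '%s', sample '%s'",
                 ids[bad[1, 1]], sample_names[bad[1, 2]]))

  role_vec <- NULL
  rep_vec <- NULL
  if (!is.null(roles)) {
    md <- read_metadata(roles)
    if ("role" %in% names(md)) {
      role_vec <- stats::setNames(md$role, md$sample_id)[sample_names]
      role_vec[is.na(role_vec)] <- "biological"
    }
    if ("replicate_of" %in% names(md)) {
      rep_vec <- stats::setNames(md$replicate_of, md$sample_id)[sample_names]
    }
  }
  count_table(m, roles = role_vec, replicate_of = rep_vec)
}

#' Write a count table as tab-separated text
#'
#' Emits the same orientation [read_count_table()] expects (features as rows),
#' with a `#OTU ID` leading header token; a read-write-read round trip
#' reproduces the table exactly.
#'
#' @param x a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", sample_ids(x)), collapse = "\t"), con, sep = "\n")
  body <- apply(x$counts, 1, function(r) paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(feature_ids(x), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a feature-to-lineage taxonomy map
#'
#' Two-column TSV: feature ID, then a semicolon-separated lineage in the
#' QIIME prefix dialect (`k__Bacteria;p__Firmicutes;...;g__Streptococcus`).
#' An empty label after a prefix (e.g. `g__`) marks the rank unassigned.
#'
#' @param path path to the taxonomy TSV.
#' @return a `taxonomy_map`: a data.frame with column `feature_id` and one
#'   column per rank (kingdom..genus), `NA` where unassigned.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  out <- data.frame(feature_id = character(0), stringsAsFactors = FALSE)
  for (r in taxonomy_ranks) out[[r]] <- character(0)
  if (length(lines) == 0) return(structure(out, class = c("taxonomy_map", "data.frame")))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) stop("taxonomy row missing feature ID or lineage")
  ids <- vapply(fields, `[[`, character(1), 1L)
  lineages <- vapply(fields, `[[`, character(1), 2L)
  parsed <- lapply(lineages, parse_lineage)
  out <- data.frame(feature_id = ids, do.call(rbind, parsed),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("taxonomy_map", "data.frame"))
}

parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  res <- stats::setNames(rep(NA_character_, length(taxonomy_ranks)), taxonomy_ranks)
  for (p in parts) {
    if (!grepl("^[a-z]__", p)) stop("unknown rank prefix in lineage token: ", p)
    pref <- substr(p, 1, 1)
    rank <- names(rank_prefixes)[rank_prefixes == pref]
    if (length(rank) == 0) stop("unknown rank prefix: ", pref, "__")
    label <- substr(p, 4, nchar(p))
    if (nzchar(label)) res[rank] <- label
  }
  as.data.frame(as.list(res), stringsAsFactors = FALSE)
}

#' Read per-sample metadata
#'
#' TSV with a `#SampleID` first column; remaining columns are covariates.
#' The reserved column `role` carries sample role flags. Empty cells and
#' `NA` are read as missing.
#'
#' @param path path to the metadata TSV.
#' @return data.frame with column `sample_id` plus covariates.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  names(md)[1] <- "sample_id"
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample ID in metadata")
  md
}

#' Collapse OTU counts to a taxonomic rank
#'
#' Features sharing the same label at `rank` are summed. Features unassigned
#' at `rank` are grouped by their full assigned lineage prefix (so the
#' unassigned genera of two different families never merge) and labelled with
#' their most resolved rank, e.g. `"Enterobacteriaceae;g__"`. Column totals
#' are conserved exactly.
#'
#' @param table a `count_table`.
#' @param tax a `taxonomy_map` covering the table's features; features absent
#'   from the map are treated as fully unassigned.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return a `count_table` with one row per collapsed taxon.
#' @export
collapse_to_rank <- function(table, tax, rank) {
  rank <- match.arg(rank, taxonomy_ranks)
  ridx <- match(rank, taxonomy_ranks)
  ids <- feature_ids(table)
  tx <- as.data.frame(tax)[match(ids, tax$feature_id), taxonomy_ranks, drop = FALSE]

  keys <- character(length(ids))
  labels <- character(length(ids))
  for (i in seq_along(ids)) {
    lin <- unlist(tx[i, seq_len(ridx)])
    if (!is.na(lin[ridx])) {
      keys[i] <- paste(lin, collapse = ";")
      labels[i] <- lin[ridx]
    } else {
      assigned <- which(!is.na(lin))
      if (length(assigned) == 0) {
        keys[i] <- "__unassigned__"
        labels[i] <- "unassigned"
      } else {
        top <- max(assigned)
        keys[i] <- paste(c(lin[seq_len(top)], rep("", ridx - top)), collapse = ";")
        labels[i] <- paste0(lin[top], ";", rank_prefixes[ridx], "__")
      }
    }
  }
  # distinct lineage keys sharing a display label get disambiguated
  ukeys <- unique(keys)
  lab_for_key <- labels[match(ukeys, keys)]
  dup <- duplicated(lab_for_key) | duplicated(lab_for_key, fromLast = TRUE)
  lab_for_key[dup] <- make.unique(lab_for_key[dup], sep = "_")

  agg <- rowsum(table$counts, group = keys, reorder = FALSE)
  rownames(agg) <- lab_for_key[match(rownames(agg), ukeys)]
  count_table(agg, roles = table$roles, replicate_of = table$replicate_of)
}
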