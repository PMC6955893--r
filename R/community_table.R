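#' Construct a validated community table
#'
#' A community table is the universal input of the package: an integer
#' matrix of sequence counts with samples as rows and taxa (ASVs, or any
#' aggregated rank) as columns.  Validation enforces non-negative integral
#' counts, unique sample and taxon identifiers, and the absence of empty
#' samples.  Taxa with zero total count carry no information for any
#' downstream statistic and are dropped with a warning (silently when
#' `quiet = TRUE`, as the synthetic generators do for never-sampled taxa).
#'
#' @param counts numeric matrix, samples x taxa, with dimnames.
#' @param quiet drop all-zero taxa without warning.
#' @return an integer matrix of class `community_table`.
#' @export
community_table <- function(counts, quiet = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count %s at row '%s', column '%s'",
                 format(counts[bad[1], bad[2]]),
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  empty_samples <- rowSums(counts) == 0
  if (any(empty_samples))
    stop("all-zero sample rows: ",
         paste(rownames(counts)[empty_samples], collapse = ", "))
  empty_taxa <- colSums(counts) == 0
  if (any(empty_taxa)) {
    if (!quiet)
      warning(sum(empty_taxa), " all-zero taxa dropped")
    counts <- counts[, !empty_taxa, drop = FALSE]
  }
  class(counts) <- c("community_table", class(counts))
  counts
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa, total count %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  cat("sample depths:", paste(range(rowSums(x)), collapse = " - "), "\n")
  invisible(x)
}

counts_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

#' Read a community count table from TSV/CSV
#'
#' The canonical dialect is a tab-separated file with taxa as rows
#' (first column the taxon id, header row the sample ids); the common
#' amplicon-table orientation.  Orientation is decided by the
#' `taxa_as_rows` flag, never guessed.
#'
#' @param path file path; comma separation is inferred from a `.csv`
#'   extension, otherwise tabs are assumed.
#' @param taxa_as_rows logical; `TRUE` (default) means rows are taxa.
#' @param quiet passed to [community_table()].
#' @return a `community_table` (samples x taxa).
#' @export
read_community_table <- function(path, taxa_as_rows = TRUE, quiet = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                   colnames(m)[bad[1, 2]], path))
    m <- num
    dimnames(m) <- list(NULL, colnames(df)[-1])
  }
  rownames(m) <- ids
  if (taxa_as_rows) m <- t(m)
  community_table(m, quiet = quiet)
}

#' Write a community table
#'
#' @param x community table.
#' @param path output file.
#' @param taxa_as_rows write taxa as rows (default, canonical dialect).
#' @export
write_community_table <- function(x, path, taxa_as_rows = TRUE) {
  m <- counts_matrix(x)
  if (taxa_as_rows) {
    out <- data.frame(taxon_id = colnames(m), t(m), check.names = FALSE)
  } else {
    out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects tab-separated text with required columns `sample_id`,
#' `environment`, `site`, `x`, `y`; any remaining columns are treated as
#' continuous environmental measurements.  Continuous variables with fewer
#' than two distinct values are dropped with a warning.
#'
#' @param path file path.
#' @return a data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "environment", "site", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("metadata missing required columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  env_cols <- setdiff(names(df), required)
  for (v in env_cols) {
    df[[v]] <- as.numeric(df[[v]])
    if (length(unique(df[[v]][!is.na(df[[v]])])) < 2) {
      warning("constant environmental variable dropped: ", v)
      df[[v]] <- NULL
    }
  }
  df$environment <- factor(df$environment)
  df$site <- factor(df$site)
  rownames(df) <- df$sample_id
  df
}

# Check a metadata table against a community table and return it ordered
# to the table's samples.
align_metadata <- function(table, metadata) {
  ids <- rownames(table)
  if (!setequal(ids, metadata$sample_id))
    stop("metadata sample ids do not match community table sample ids")
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}

#' Read a taxonomy table
#'
#' Accepts either a `taxon_id` column plus a `lineage` column with a
#' semicolon-delimited lineage, or `taxon_id` plus one column per rank.
#' Empty or missing rank labels are replaced by the unassigned token.
#'
#' @param path file path.
#' @param unassigned token for missing rank labels.
#' @return a data.frame: `taxon_id` plus one column per rank.
#' @export
read_taxonomy_table <- function(path, unassigned = "Unassigned") {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) stop("taxonomy needs a taxon_id column")
  if ("lineage" %in% names(df)) {
    parts <- strsplit(df$lineage, ";", fixed = TRUE)
    depth <- max(lengths(parts))
    ranks <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")[seq_len(depth)]
    mat <- t(vapply(parts, function(p) {
      p <- trimws(p)
      c(p, rep(unassigned, depth - length(p)))
    }, character(depth)))
    df <- data.frame(taxon_id = df$taxon_id, mat, stringsAsFactors = FALSE)
    names(df) <- c("taxon_id", ranks)
  }
  for (v in setdiff(names(df), "taxon_id"))
    df[[v]][is.na(df[[v]]) | df[[v]] == ""] <- unassigned
  df
}

#' Rarefy a community table to even depth
#'
#' Random sub-sampling without replacement (multivariate hypergeometric)
#' within each sample, to standardise uneven sequencing effort.  Each
#' sample uses an independent random substream derived deterministically
#' from the master seed and the sample's position, so results do not
#' depend on the presence or order of other samples.
#'
#' @param x community table.
#' @param depth target depth; default the smallest sample total.
#' @param seed master seed (integer).
#' @param quiet drop post-rarefaction all-zero taxa without warning.
#' @return a rarefied `community_table` whose rows all sum to `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = 1, quiet = FALSE) {
  m <- counts_matrix(x)
  totals <- rowSums(m)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  shallow <- totals < depth
  if (any(shallow))
    stop("samples shallower than requested depth ", depth, ": ",
         paste(rownames(m)[shallow], collapse = ", "))
  out <- m
  for (i in seq_len(nrow(m))) {
    if (totals[i] == depth) next
    set.seed(derive_seed(seed, i))
    pool <- rep.int(seq_len(ncol(m)), m[i, ])
    keep <- pool[sample.int(length(pool), depth)]
    out[i, ] <- tabulate(keep, nbins = ncol(m))
  }
  community_table(out, quiet = quiet)
}

#' Aggregate taxa to a higher taxonomic rank
#'
#' Counts are summed over taxa sharing the same label at `rank`; taxa with
#' the unassigned token are pooled under it.  The grand total of counts is
#' conserved exactly.
#'
#' @param x community table.
#' @param taxonomy data.frame from [read_taxonomy_table()].
#' @param rank rank column name to aggregate at.
#' @param missing what to do with table taxa absent from the taxonomy:
#'   `"error"` (default) or `"pool"` under the unassigned token.
#' @param unassigned the unassigned token.
#' @return a `community_table` with rank labels as taxa.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank, missing = c("error", "pool"),
                              unassigned = "Unassigned") {
  missing <- match.arg(missing)
  if (!rank %in% names(taxonomy))
    stop("rank '", rank, "' not present in taxonomy")
  m <- counts_matrix(x)
  labels <- taxonomy[[rank]][match(colnames(m), taxonomy$taxon_id)]
  absent <- is.na(labels)
  if (any(absent)) {
    if (missing == "error")
      stop("taxa missing from taxonomy: ",
           paste(utils::head(colnames(m)[absent], 5), collapse = ", "))
    labels[absent] <- unassigned
  }
  agg <- t(rowsum(t(m), group = labels))
  stopifnot(sum(as.numeric(agg)) == sum(as.numeric(m)))
  community_table(agg, quiet = TRUE)
}
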