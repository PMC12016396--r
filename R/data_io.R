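# Reading sequences and interaction tables, negative sampling, CV folds.

#' Read RNA sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a sequence table.
#' Sequences are uppercased and DNA-style `T` is mapped to `U`, so files in
#' either the RNA or the DNA alphabet work unchanged. Any residue outside
#' `A/C/G/U` after normalization is an error naming the offending record.
#' Identifiers are the first whitespace-delimited token of the header line
#' and must be unique within the file.
#'
#' @param path path to a FASTA file.
#' @param kind `"circRNA"` or `"miRNA"`; stored alongside each record.
#' @return a `data.frame` of class `cmi_sequences` with columns `id`, `seq`,
#'   `kind`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "AGCU", ">c2", "ggau"), fa)
#' read_fasta(fa, "circRNA")
read_fasta <- function(path, kind = c("circRNA", "miRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) stopf("FASTA file is empty: %s", path)
  if (!startsWith(trimws(lines[first]), ">")) {
    stopf("malformed FASTA header at line %d of %s: expected '>'", first, path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- trimws(vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1))
  if (anyDuplicated(ids)) {
    stopf("duplicate sequence id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("acgut", "ACGUT", as.character(set))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stopf("sequence(s) with characters outside A/C/G/U/T: %s",
          paste(ids[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stopf("empty sequence(s): %s", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  structure(
    data.frame(id = ids, seq = unname(seqs), kind = kind,
               stringsAsFactors = FALSE),
    class = c("cmi_sequences", "data.frame")
  )
}

#' Construct an interaction table
#'
#' @param circRNA,miRNA character vectors of equal length.
#' @param label 0/1 vector (default all 1).
#' @param provenance `"observed"` or `"sampled_negative"` per pair.
#' @return `data.frame` of class `cmi_interactions` with columns `circRNA`,
#'   `miRNA`, `label`, `provenance`.
#' @export
interaction_table <- function(circRNA, miRNA,
                              label = rep(1L, length(circRNA)),
                              provenance = ifelse(label == 1L, "observed",
                                                  "sampled_negative")) {
  stopifnot(length(circRNA) == length(miRNA),
            length(label) == length(circRNA))
  if (!all(label %in% c(0L, 1L))) stopf("labels must be 0 or 1")
  key <- paste(circRNA, miRNA, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate (circRNA, miRNA) pair(s): %s",
          paste(unique(sub("\r", " / ", key[duplicated(key)])), collapse = ", "))
  }
  if (!any(label == 1L)) stopf("interaction table must contain at least one positive pair")
  structure(
    data.frame(circRNA = as.character(circRNA), miRNA = as.character(miRNA),
               label = as.integer(label), provenance = as.character(provenance),
               stringsAsFactors = FALSE),
    class = c("cmi_interactions", "data.frame")
  )
}

.header_tokens <- list(
  circ = c("circrna", "circ", "circrna_id", "circ_id", "circbase_id", "circbase"),
  mir  = c("mirna", "mir", "mirna_id", "mir_id", "mirbase_id", "mirbase")
)

#' Read an interaction table from delimited text
#'
#' Reads a TSV/CSV file whose first two columns are circRNA and miRNA
#' identifiers. A header row is detected when the first row's two values are
#' recognized column names (`circRNA`/`miRNA` and common variants) rather
#' than identifiers. An optional third column holds 0/1 labels (as written
#' by [write_interactions()]); without it all pairs are read as positives.
#' Exact duplicate rows are collapsed with a message; identifiers must
#' resolve against the supplied id sets (exact match after whitespace
#' stripping — no fuzzy aliasing, so a typo fails loudly instead of
#' mis-joining).
#'
#' @param path delimited text file.
#' @param circ_ids,mir_ids character vectors of known identifiers.
#' @return a `cmi_interactions` table; attribute `n_duplicates` records how
#'   many duplicate rows were collapsed.
#' @export
read_interactions <- function(path, circ_ids, mir_ids) {
  if (!file.exists(path)) stopf("interaction file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2) stopf("interaction file needs at least two columns: %s", path)
  for (j in seq_len(ncol(dt))) dt[[j]] <- trimws(dt[[j]])
  if (nrow(dt) >= 1) {
    h1 <- tolower(dt[1, 1]); h2 <- tolower(dt[1, 2])
    if (h1 %in% .header_tokens$circ && h2 %in% .header_tokens$mir) {
      dt <- dt[-1, , drop = FALSE]
    }
  }
  if (nrow(dt) == 0) stopf("interaction file has no data rows: %s", path)
  circ <- dt[[1]]; mir <- dt[[2]]
  label <- if (ncol(dt) >= 3 && all(dt[[3]] %in% c("0", "1"))) {
    as.integer(dt[[3]])
  } else {
    rep(1L, nrow(dt))
  }
  key <- paste(circ, mir, label, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(sprintf("read_interactions: collapsed %d exact duplicate row(s)", n_dup))
    circ <- circ[!dup]; mir <- mir[!dup]; label <- label[!dup]
  }
  unknown_c <- setdiff(unique(circ), circ_ids)
  unknown_m <- setdiff(unique(mir), mir_ids)
  if (length(unknown_c) || length(unknown_m)) {
    stopf("unresolvable identifier(s): %s",
          paste(c(unknown_c, unknown_m), collapse = ", "))
  }
  tab <- interaction_table(circ, mir, label)
  attr(tab, "n_duplicates") <- n_dup
  tab
}

#' Write an interaction table as TSV
#'
#' Columns `circRNA`, `miRNA`, `label`, with header; re-reading with
#' [read_interactions()] reproduces the pairs and labels exactly.
#'
#' @param table a `cmi_interactions` table.
#' @param path output path.
#' @export
write_interactions <- function(table, path) {
  out <- data.frame(circRNA = table$circRNA, miRNA = table$miRNA,
                    label = table$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample negative pairs uniformly from the unobserved pair space
#'
#' Extends a table of observed positives with `round(ratio * n_positive)`
#' label-0 pairs drawn uniformly without replacement from the (circRNA,
#' miRNA) pairs not present in the table. Deterministic for a fixed seed.
#'
#' @param table a `cmi_interactions` table (its positives define the
#'   forbidden set; existing negatives are also never re-drawn).
#' @param circ_ids,mir_ids identifier universes defining the pair space.
#' @param ratio negatives per positive (default 1, the convention of the
#'   comparator CMI models, which keeps accuracy-style metrics interpretable).
#' @param seed integer seed.
#' @return the extended `cmi_interactions` table.
#' @export
sample_negatives <- function(table, circ_ids, mir_ids, ratio = 1, seed = 1L) {
  stopifnot(ratio > 0)
  n_pos <- sum(table$label == 1L)
  n_neg <- round(ratio * n_pos)
  nc <- length(circ_ids); nm <- length(mir_ids)
  avail <- nc * nm - nrow(table)
  if (avail < n_neg) {
    stopf("pair space exhausted: %d unobserved pairs available; maximum feasible ratio is %.4g",
          avail, avail / n_pos)
  }
  # index pairs 0..(nc*nm-1): ci = idx %% nc, mi = idx %/% nc
  taken_idx <- (match(table$miRNA, mir_ids) - 1L) * nc +
    (match(table$circRNA, circ_ids) - 1L)
  free <- setdiff(seq_len(nc * nm) - 1L, taken_idx)
  pick <- with_seed(seed, sample(free, n_neg))
  neg_c <- circ_ids[(pick %% nc) + 1L]
  neg_m <- mir_ids[(pick %/% nc) + 1L]
  interaction_table(c(table$circRNA, neg_c), c(table$miRNA, neg_m),
                    c(table$label, rep(0L, n_neg)),
                    c(table$provenance, rep("sampled_negative", n_neg)))
}

#' Random k-fold partition, optionally label-stratified
#'
#' Assigns each of `n_pairs` indices to one of `k` folds so that fold sizes
#' differ by at most one. With `stratify_labels`, indices are shuffled
#' within each label class and folds are dealt cyclically across the
#' concatenated classes, so both the overall fold sizes and the per-class
#' counts per fold differ by at most one — per-fold positive fractions then
#' track the global fraction.
#'
#' @param n_pairs number of items to split.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratify_labels optional vector of labels (same length as
#'   `n_pairs`).
#' @return object of class `cmi_folds`: list with `assignments` (integer
#'   vector in `1..k`), `k`, `seed`.
#' @export
make_folds <- function(n_pairs, k = 5L, seed = 1L, stratify_labels = NULL) {
  if (k < 2L) stopf("k must be at least 2")
  if (k > n_pairs) stopf("k = %d exceeds the number of pairs (%d)", k, n_pairs)
  if (!is.null(stratify_labels) && length(stratify_labels) != n_pairs) {
    stopf("stratify_labels must have length n_pairs")
  }
  assignments <- integer(n_pairs)
  with_seed(seed, {
    offset <- sample.int(k, 1L) - 1L
    strata <- if (is.null(stratify_labels)) list(seq_len(n_pairs))
              else split(seq_len(n_pairs), stratify_labels)
    for (idx in strata) {
      idx <- if (length(idx) > 1L) sample(idx) else idx
      assignments[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(assignments = assignments, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cmi_folds")
}

#' Export fold assignments as CSV
#'
#' Two columns: `pair_index` (1-based row index into the table the folds
#' were made for) and `fold`.
#'
#' @param folds a `cmi_folds` object.
#' @param path output path.
#' @export
write_folds <- function(folds, path) {
  utils::write.csv(data.frame(pair_index = seq_along(folds$assignments),
                              fold = folds$assignments),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
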