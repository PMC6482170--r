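# TSV dialect shared by all readers: tab-separated, UTF-8, '#' comments.
.readTsvLines <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a lncRNA-protein interaction edge list
#'
#' Reads a 2-column TSV (lncRNA id, protein id), collapses duplicate edges,
#' and returns a [BipartiteNetwork-class] whose axes are ordered by first
#' appearance in the file. Lines starting with `#` are ignored.
#'
#' @param path path to the edge-list TSV.
#' @param header logical; skip a header line.
#' @return A [BipartiteNetwork-class].
#' @seealso [filterMinDegree()] for the minimum-degree cleaning step.
#' @export
readInteractions <- function(path, header = FALSE) {
  tsv <- .readTsvLines(path)
  lines <- tsv$lines
  lineno <- tsv$lineno
  if (header && length(lines)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) stop("no edges in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad)) {
    stop("malformed row at line ", lineno[bad[1]], " of '", path,
      "': expected at least 2 tab-separated fields")
  }
  BipartiteNetwork(data.frame(
    lncrna = vapply(fields, `[[`, "", 1L),
    protein = vapply(fields, `[[`, "", 2L),
    stringsAsFactors = FALSE
  ))
}

#' Write a network back to an edge-list TSV
#'
#' Edges are emitted lncRNA by lncRNA in network order (proteins in row
#' order within each lncRNA). Reading the file back always recovers the
#' same edge content; for a network whose axis order came from
#' [readInteractions()] (the canonical order) the round trip is the exact
#' identity. A network constructed with some other axis order may be
#' relabelled once, since no edge ordering can encode two independent
#' first-appearance sequences in general.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path output path.
#' @export
writeInteractions <- function(net, path) {
  I <- interactionMatrix(net)
  idx <- which(I == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  utils::write.table(
    data.frame(lncrna = lncrnaIds(net)[idx[, "col"]],
      protein = proteinIds(net)[idx[, "row"]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove low-degree nodes until a fixed point
#'
#' Iteratively removes proteins and lncRNAs whose degree (row/column sum of
#' the interaction matrix) falls below `minDegree`, repeating until no node
#' is below threshold: removing a node can drop a neighbour below the
#' threshold, so a single pass is not self-consistent. With the default
#' `minDegree = 2` this implements the cleaning rule that every retained
#' node supports leave-one-out evaluation (at least one training edge
#' remains when one is held out). The operation is idempotent.
#'
#' @param net a [BipartiteNetwork-class].
#' @param minDegree minimum degree to survive, `>= 1`.
#' @return The filtered [BipartiteNetwork-class].
#' @export
filterMinDegree <- function(net, minDegree = 2L) {
  stopifnot(minDegree >= 1L)
  I <- interactionMatrix(net)
  repeat {
    keepP <- rowSums(I) >= minDegree
    keepL <- colSums(I) >= minDegree
    if (all(keepP) && all(keepL)) break
    I <- I[keepP, keepL, drop = FALSE]
    if (nrow(I) == 0L || ncol(I) == 0L) {
      stop("network emptied by filtering (minDegree = ", minDegree, ")")
    }
  }
  new("BipartiteNetwork", proteinIds = rownames(I), lncrnaIds = colnames(I),
    I = I)
}

#' Read protein-protein interaction scores
#'
#' Reads a 3-column TSV (protein id, protein id, score) and materializes the
#' symmetric non-negative score matrix over `proteinIds(net)`. Pairs listed
#' in both orders must agree in score (a redundancy conflict is an error;
#' the duplicate is kept once). Rows naming proteins absent from the network
#' are skipped with a single warning giving the count. Unlisted pairs are 0;
#' the diagonal is 0 unless a self-score is listed.
#'
#' @param path path to the PPI TSV.
#' @param net the interaction network whose protein axis orders the matrix.
#' @param header logical; skip a header line.
#' @return Symmetric numeric matrix, `nProteins(net)` square.
#' @export
readPPIScores <- function(path, net, header = FALSE) {
  tsv <- .readTsvLines(path)
  lines <- tsv$lines
  lineno <- tsv$lineno
  if (header && length(lines)) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  ids <- proteinIds(net)
  AP <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (!length(lines)) return(AP)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 3L)
  if (length(bad)) {
    stop("malformed row at line ", lineno[bad[1]], " of '", path,
      "': expected 3 tab-separated fields")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(s)) stop("non-numeric PPI score at line ", lineno[which(is.na(s))[1]])
  if (any(s <= 0)) stop("PPI scores must be positive")
  known <- a %in% ids & b %in% ids
  if (any(!known)) {
    warning(sum(!known), " PPI row(s) with protein ids absent from the ",
      "network were skipped")
  }
  a <- a[known]; b <- b[known]; s <- s[known]
  seen <- new.env(parent = emptyenv())
  for (r in seq_along(a)) {
    key <- paste(sort(c(a[r], b[r])), collapse = "\r")
    prev <- seen[[key]]
    if (!is.null(prev)) {
      if (prev != s[r]) {
        stop("conflicting duplicate PPI scores for pair (", a[r], ", ",
          b[r], "): ", prev, " vs ", s[r])
      }
      next
    }
    seen[[key]] <- s[r]
    AP[a[r], b[r]] <- s[r]
    AP[b[r], a[r]] <- s[r]
  }
  AP
}

#' Read lncRNA expression profiles
#'
#' Reads a TSV matrix whose first column holds lncRNA ids and whose header
#' names the tissues/cell types. Rows are reordered to match
#' `lncrnaIds(net)`; rows for lncRNAs not in the network are dropped with a
#' warning, and a network lncRNA missing from the table is an error. Missing
#' values are an error (profiles must be complete).
#'
#' @param path path to the expression TSV.
#' @param net the interaction network whose lncRNA axis orders the rows.
#' @return Numeric matrix, `nLncrnas(net)` rows by T tissue columns, with
#'   rownames equal to `lncrnaIds(net)`.
#' @export
readExpression <- function(path, net) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
    comment.char = "#", check.names = FALSE)
  E <- as.matrix(tab)
  if (!is.numeric(E)) stop("expression values must be numeric")
  if (anyNA(E)) stop("missing values in expression profiles")
  ids <- lncrnaIds(net)
  missing <- setdiff(ids, rownames(E))
  if (length(missing)) {
    stop("lncRNAs missing from expression table: ",
      paste(missing, collapse = ", "))
  }
  extra <- setdiff(rownames(E), ids)
  if (length(extra)) {
    warning(length(extra), " expression row(s) for lncRNAs absent from the ",
      "network were dropped")
  }
  E[ids, , drop = FALSE]
}

#' Write per-lncRNA protein rankings
#'
#' Emits a 4-column TSV (lncrna_id, protein_id, score, rank) with the rank
#' computed per lncRNA in descending score order, ties broken by protein id
#' lexicographically (stable). With `excludeKnown = TRUE` the known
#' interactions of each lncRNA are omitted before ranking, leaving only
#' novel candidates.
#'
#' @param scores numeric score matrix, `nProteins(net)` by `nLncrnas(net)`.
#' @param net the [BipartiteNetwork-class] providing ids (and known edges
#'   when `excludeKnown`).
#' @param path output path.
#' @param excludeKnown drop known interactions from the ranked lists.
#' @return The path, invisibly.
#' @export
writeRankings <- function(scores, net, path, excludeKnown = FALSE) {
  stopifnot(nrow(scores) == nProteins(net), ncol(scores) == nLncrnas(net))
  I <- interactionMatrix(net)
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    keep <- if (excludeKnown) which(I[, j] == 0) else seq_len(nrow(scores))
    if (!length(keep)) return(NULL)
    pid <- proteinIds(net)[keep]
    sc <- scores[keep, j]
    ord <- order(-sc, pid, method = "radix")
    data.frame(lncrna = lncrnaIds(net)[j], protein = pid[ord],
      score = sc[ord], rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a rankings TSV written by [writeRankings()]
#'
#' @param path path to the rankings TSV.
#' @return data.frame with columns lncrna, protein, score, rank.
#' @export
readRankings <- function(path) {
  utils::read.delim(path, header = TRUE, comment.char = "#",
    stringsAsFactors = FALSE)
}

#' Export a similarity matrix as TSV
#'
#' Square matrix with an id header and id-labelled rows, for inspection.
#'
#' @param M symmetric similarity matrix with dimnames.
#' @param path output path.
#' @export
writeSimilarity <- function(M, path) {
  stopifnot(nrow(M) == ncol(M), !is.null(rownames(M)))
  utils::write.table(
    data.frame(id = rownames(M), M, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
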