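# Byte-pair-encoding segmentation for SMILES and protein sequences.
#
# A trained segmenter is an ordered list of merge rules. Training repeatedly
# counts adjacent token pairs over the whole corpus and merges the most
# frequent pair into a new multi-character token, until `threshold` merges
# have been learned. Each corpus line is one unbroken token stream: merges
# may span any adjacent positions within a sequence but never across
# sequences, and no end-of-word marker is used (molecular strings have no
# word structure).

PAIR_SEP <- "\x1f"

#' Train a byte-pair-encoding segmenter
#'
#' Learns an ordered merge table from a corpus of sequences (drug SMILES or
#' protein strings, one sequence per element). Starting from single
#' characters, the most frequent adjacent token pair is merged into a new
#' token; ties in frequency are broken by taking the lexicographically
#' smallest `(left, right)` pair (C-locale byte order), which makes training
#' fully deterministic. Training stops after `threshold` merges, or earlier
#' when the best remaining pair occurs fewer than `min_frequency` times
#' (merging a once-seen pair compresses nothing).
#'
#' @param corpus Character vector of sequences, one per element. Must be
#'   non-empty and contain no empty strings.
#' @param threshold Maximum number of merge operations (the vocabulary grows
#'   by one token per merge). Non-negative integer.
#' @param min_frequency Minimum corpus frequency a pair must reach to be
#'   merged; default 2. Set to 1 to merge down to single occurrences.
#' @return An object of class `"bpe_merges"`: a list with `merges` (a list of
#'   length-2 character vectors in learned order), `alphabet` (sorted unique
#'   single characters seen in training) and `threshold`.
#' @examples
#' bp <- bpe_train(c("CCOCCO", "CCN"), threshold = 2)
#' bp$merges
#' @seealso [bpe_segment()], [bpe_vocabulary()]
#' @export
bpe_train <- function(corpus, threshold, min_frequency = 2L) {
  if (!is.character(corpus) || length(corpus) == 0L) {
    stop("`corpus` must be a non-empty character vector", call. = FALSE)
  }
  if (anyNA(corpus) || any(!nzchar(corpus))) {
    stop("`corpus` must not contain NA or empty sequences", call. = FALSE)
  }
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L) {
    stop("`threshold` must be a non-negative integer", call. = FALSE)
  }

  seqs <- strsplit(corpus, "", fixed = TRUE)
  alphabet <- sort(unique(unlist(seqs)), method = "radix")
  merges <- vector("list", threshold)
  n_merges <- 0L

  while (n_merges < threshold) {
    best <- best_pair(seqs)
    if (is.null(best) || best$count < min_frequency) break
    n_merges <- n_merges + 1L
    merges[[n_merges]] <- best$pair
    seqs <- lapply(seqs, apply_merge, left = best$pair[1L], right = best$pair[2L])
  }

  structure(
    list(merges = merges[seq_len(n_merges)], alphabet = alphabet,
         threshold = threshold),
    class = "bpe_merges"
  )
}

# Most frequent adjacent pair across all sequences; overlapping occurrences
# all count (so "aaaa" contributes 3 to ("a","a")). Ties break to the
# byte-order smallest (left, right).
best_pair <- function(seqs) {
  keys <- unlist(lapply(seqs, function(s) {
    n <- length(s)
    if (n < 2L) return(character(0))
    paste(s[-n], s[-1L], sep = PAIR_SEP)
  }), use.names = FALSE)
  if (length(keys) == 0L) return(NULL)
  counts <- table(keys)
  top <- names(counts)[counts == max(counts)]
  parts <- strsplit(top, PAIR_SEP, fixed = TRUE)
  lefts <- vapply(parts, `[`, "", 1L)
  rights <- vapply(parts, `[`, "", 2L)
  pick <- order(lefts, rights, method = "radix")[1L]
  list(pair = c(lefts[pick], rights[pick]), count = as.integer(max(counts)))
}

# Replace non-overlapping (left, right) adjacencies by their concatenation,
# scanning left to right.
apply_merge <- function(tokens, left, right) {
  n <- length(tokens)
  if (n < 2L) return(tokens)
  hits <- which(tokens[-n] == left & tokens[-1L] == right)
  if (length(hits) == 0L) return(tokens)
  keep <- hits[1L]
  if (length(hits) > 1L) {
    for (h in hits[-1L]) {
      if (h > keep[length(keep)] + 1L) keep <- c(keep, h)
    }
  }
  tokens[keep] <- paste0(left, right)
  tokens[-(keep + 1L)]
}

#' Segment sequences with a trained merge table
#'
#' Splits each sequence into single characters and replays the learned merges
#' in order, each applied greedily left to right. Concatenating the returned
#' tokens always reproduces the input exactly; characters never seen in
#' training simply pass through as single-character tokens.
#'
#' @param x Character vector of sequences to segment.
#' @param bpe A `"bpe_merges"` object from [bpe_train()], or a
#'   `"bpe_vocab"` object (its merge table is used).
#' @return A list of character vectors, one per input sequence.
#' @examples
#' bp <- bpe_train(c("abab", "abab"), threshold = 1)
#' bpe_segment("abab", bp)[[1]]  # "ab" "ab"
#' @export
bpe_segment <- function(x, bpe) {
  if (!is.character(x) || anyNA(x) || any(!nzchar(x))) {
    stop("`x` must be a character vector of non-empty sequences", call. = FALSE)
  }
  merges <- bpe$merges
  if (!is.list(merges)) stop("`bpe` has no merge table", call. = FALSE)
  out <- lapply(strsplit(x, "", fixed = TRUE), function(tokens) {
    for (m in merges) tokens <- apply_merge(tokens, m[1L], m[2L])
    tokens
  })
  names(out) <- names(x)
  out
}

#' Build an integer vocabulary from a merge table
#'
#' Assigns every producible token a positive integer id: the training
#' alphabet first, in sorted order, then the merged tokens in merge order.
#' Id 0 is reserved for padding and is never assigned to a token; unknown
#' tokens at encode time map to the reserved id `size + 1`.
#'
#' @param bpe A `"bpe_merges"` object from [bpe_train()].
#' @return An object of class `"bpe_vocab"`: a list with `token_to_id`
#'   (named integer vector), `pad_id` (0), `unk_id` (`size + 1`), `size`
#'   (number of real tokens), plus the `merges`, `alphabet` and `threshold`
#'   needed to segment new sequences.
#' @examples
#' vocab <- bpe_vocabulary(bpe_train(c("abab", "abab"), threshold = 1))
#' vocab$token_to_id  # a=1 b=2 ab=3
#' @export
bpe_vocabulary <- function(bpe) {
  stopifnot(inherits(bpe, "bpe_merges"))
  merged <- vapply(bpe$merges, function(m) paste0(m[1L], m[2L]), "")
  tokens <- c(bpe$alphabet, merged)
  ids <- seq_along(tokens)
  names(ids) <- tokens
  structure(
    list(token_to_id = ids, pad_id = 0L, unk_id = length(tokens) + 1L,
         size = length(tokens), merges = bpe$merges, alphabet = bpe$alphabet,
         threshold = bpe$threshold),
    class = "bpe_vocab"
  )
}

#' Encode a token sequence as a fixed-length integer vector
#'
#' Maps tokens to their vocabulary ids, truncates on the right to at most
#' `maxlen` tokens, and right-pads with 0 up to `maxlen`. Tokens absent from
#' the vocabulary get the reserved unknown id.
#'
#' @param tokens Character vector of tokens (one segmented sequence), or a
#'   single unsegmented string which is segmented with the vocabulary's
#'   merge table first.
#' @param vocab A `"bpe_vocab"` object.
#' @param maxlen Fixed output length `l` (positive integer).
#' @return Integer vector of length `maxlen` with attribute `true_length`,
#'   the number of non-padding slots.
#' @examples
#' vocab <- bpe_vocabulary(bpe_train("CCO", threshold = 0))
#' bpe_encode(c("C", "O"), vocab, maxlen = 5)
#' @export
bpe_encode <- function(tokens, vocab, maxlen) {
  stopifnot(inherits(vocab, "bpe_vocab"))
  maxlen <- as.integer(maxlen)
  if (is.na(maxlen) || maxlen < 1L) stop("`maxlen` must be >= 1", call. = FALSE)
  if (length(tokens) == 1L && !tokens %in% names(vocab$token_to_id) &&
      nchar(tokens) > 1L) {
    tokens <- bpe_segment(tokens, vocab)[[1L]]
  }
  ids <- unname(vocab$token_to_id[tokens])
  ids[is.na(ids)] <- vocab$unk_id
  n <- min(length(ids), maxlen)
  out <- integer(maxlen)
  if (n > 0L) out[seq_len(n)] <- ids[seq_len(n)]
  attr(out, "true_length") <- n
  out
}

#' Encode many sequences into an id matrix
#'
#' Convenience wrapper around [bpe_segment()] and [bpe_encode()]: segments
#' each input string and stacks the padded id vectors into a matrix.
#'
#' @inheritParams bpe_segment
#' @param vocab A `"bpe_vocab"` object.
#' @param maxlen Fixed encoded length per sequence.
#' @return Integer matrix with one row per sequence and `maxlen` columns,
#'   with attribute `true_lengths`.
#' @export
bpe_encode_matrix <- function(x, vocab, maxlen) {
  toks <- bpe_segment(x, vocab)
  rows <- lapply(toks, bpe_encode, vocab = vocab, maxlen = maxlen)
  out <- do.call(rbind, lapply(rows, as.vector))
  rownames(out) <- names(x)
  attr(out, "true_lengths") <- vapply(rows, attr, 0L, "true_length")
  out
}

#' @export
print.bpe_merges <- function(x, ...) {
  cat("BPE merge table:", length(x$merges), "merges (threshold",
      x$threshold, "),", length(x$alphabet), "alphabet symbols\n")
  if (length(x$merges) > 0L) {
    show <- utils::head(x$merges, 10L)
    cat("  first merges:",
        paste(vapply(show, function(m) paste0(m[1L], "+", m[2L]), ""),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.bpe_vocab <- function(x, ...) {
  cat("BPE vocabulary:", x$size, "tokens (pad id 0, unk id", x$unk_id, "),",
      length(x$merges), "merges\n")
  invisible(x)
}

#' Write a vocabulary to JSON
#'
#' Serializes a `"bpe_vocab"` (or a bare merge table) to a diff-stable JSON
#' file with fields `threshold_T`, `alphabet`, `merges` and `token_to_id`,
#' replayable on any platform.
#'
#' @param vocab A `"bpe_vocab"` object (a `"bpe_merges"` object is converted
#'   with [bpe_vocabulary()] first).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bpe_vocab <- function(vocab, path) {
  if (inherits(vocab, "bpe_merges")) vocab <- bpe_vocabulary(vocab)
  stopifnot(inherits(vocab, "bpe_vocab"))
  obj <- list(
    threshold_T = vocab$threshold,
    alphabet = vocab$alphabet,
    merges = lapply(vocab$merges, as.character),
    token_to_id = as.list(vocab$token_to_id)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#'
#' @param path A JSON file written by [write_bpe_vocab()].
#' @return A `"bpe_vocab"` object.
#' @export
read_bpe_vocab <- function(path) {
  obj <- jsonlite::read_json(path)
  ids <- vapply(obj$token_to_id, as.integer, 0L)
  structure(
    list(token_to_id = ids, pad_id = 0L, unk_id = length(ids) + 1L,
         size = length(ids),
         merges = lapply(obj$merges, function(m) as.character(unlist(m))),
         alphabet = as.character(unlist(obj$alphabet)),
         threshold = as.integer(obj$threshold_T)),
    class = "bpe_vocab"
  )
}

#' Read a segmentation corpus
#'
#' Reads sequences for BPE training: either plain text with one sequence per
#' line, or FASTA (headers ignored, sequence lines of one record are
#' concatenated). Empty lines are dropped.
#'
#' @param path File path.
#' @param format `"auto"` (FASTA when the first non-empty line starts with
#'   `>`), `"text"` or `"fasta"`.
#' @return Character vector of sequences.
#' @export
read_corpus <- function(path, format = c("auto", "text", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such corpus file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("corpus file is empty: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (startsWith(trimws(lines[1L]), ">")) "fasta" else "text"
  }
  if (format == "text") return(trimws(lines))
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) stop("no FASTA headers found in ", path, call. = FALSE)
  rec <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 function(x) paste(trimws(x), collapse = ""), "")
  unname(seqs[nzchar(seqs)])
}
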