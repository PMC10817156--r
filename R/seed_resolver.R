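# Seed resolution from protein sequence: a cd-hit-style greedy identity
# clustering builds a non-redundant per-group reference, and a query is
# assigned to the group of its best-matching representative.
#
# Identity convention (cd-hit's): matching positions divided by the length
# of the shorter sequence, under global alignment. Alignment parameters are
# BLAST-like defaults: BLOSUM62 with affine gaps, open 11 / extend 1.

.blosum62_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_env$mat <- e$BLOSUM62
  }
  .blosum62_env$mat
}

# identity of one sequence against a set, as matching positions divided by
# the full length of the shorter sequence (cd-hit's denominator, applied to
# local alignments as well so that fragment matches cannot inflate identity)
.identity_vs <- function(targets, query, type) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(targets),
    subject = Biostrings::AAString(query),
    type = type, substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  list(identity = Biostrings::nmatch(aln) / pmin(nchar(targets), nchar(query)),
       score = Biostrings::score(aln))
}

#' Greedy identity clustering of protein sequences
#'
#' cd-hit-style incremental clustering: sequences are sorted by length
#' descending (ties by id ascending); each sequence joins the first existing
#' representative with global-alignment identity at or above
#' \code{threshold}, otherwise it founds a new representative.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param threshold Identity fraction in (0, 1]; default 0.8.
#' @return Named character vector of representative sequences, in creation
#'   order. Representatives are pairwise below the threshold; every input
#'   sequence has identity at or above the threshold to some representative.
#' @export
greedy_cluster <- function(sequences, threshold = 0.8) {
  threshold <- .check_fraction(threshold, "threshold")
  if (length(sequences) == 0L) return(stats::setNames(character(), character()))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    .usage_error("'sequences' must be a named character vector")
  sequences <- toupper(sequences)
  .validate_protein(unname(sequences), names(sequences))
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- sequences[1L]
  for (i in seq_along(sequences)[-1L]) {
    idt <- .identity_vs(unname(reps), sequences[[i]], "global")$identity
    if (!any(idt >= threshold)) reps <- c(reps, sequences[i])
  }
  reps
}

#' Build a per-group non-redundant reference
#'
#' Applies [greedy_cluster()] independently within each orthologous group.
#'
#' @param memberships Named list mapping group id to a named character
#'   vector of member protein sequences.
#' @param threshold Identity threshold used at build time; default 0.8.
#' @return Object of class \code{reference_db}: list with
#'   \code{representatives} (data frame \code{group_id}, \code{protein_id},
#'   \code{sequence}) and \code{identity_threshold}.
#' @export
build_reference <- function(memberships, threshold = 0.8) {
  threshold <- .check_fraction(threshold, "threshold")
  if (length(memberships) == 0L)
    return(structure(list(representatives = data.frame(group_id = character(),
                                                       protein_id = character(),
                                                       sequence = character(),
                                                       stringsAsFactors = FALSE),
                          identity_threshold = threshold),
                     class = "reference_db"))
  if (any(!.is_group_id(names(memberships))))
    .validation_error("group ids must match COG/KOG + 4 digits")
  reps <- lapply(names(memberships), function(g) {
    r <- greedy_cluster(memberships[[g]], threshold)
    message(sprintf("build_reference: %s reduced %d -> %d sequences",
                    g, length(memberships[[g]]), length(r)))
    data.frame(group_id = g, protein_id = names(r), sequence = unname(r),
               stringsAsFactors = FALSE)
  })
  structure(list(representatives = do.call(rbind, reps),
                 identity_threshold = threshold),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db: %d representatives in %d groups, identity threshold %.2f>\n",
              nrow(x$representatives), length(unique(x$representatives$group_id)),
              x$identity_threshold))
  invisible(x)
}

.kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Resolve a query protein to its orthologous group
#'
#' Locally aligns the query (BLOSUM62, gap open 11 / extend 1) against all
#' representatives that share at least one 5-mer with it (a pure-speedup
#' prescreen), ranks hits by identity, then alignment score, then ascending
#' group id, and returns the top hit if its identity reaches
#' \code{min_identity}.
#'
#' @param query Single named character element (an amino-acid sequence).
#' @param refdb A \code{reference_db}.
#' @param min_identity Acceptance threshold, default 0.5; hits below the
#'   build threshold are flagged low-confidence.
#' @return A one-row data frame of class \code{seed_hit} with columns
#'   \code{group_id}, \code{representative_id}, \code{identity},
#'   \code{score}, \code{low_confidence}; or \code{NULL} if no hit.
#' @export
resolve_seed <- function(query, refdb, min_identity = 0.5) {
  stopifnot(inherits(refdb, "reference_db"))
  min_identity <- .check_fraction(min_identity, "min_identity")
  if (nrow(refdb$representatives) == 0L) .usage_error("reference database is empty")
  if (length(query) != 1L || !is.character(query))
    .usage_error("'query' must be a single character sequence")
  query <- toupper(query)
  .validate_protein(unname(query), names(query) %||% "query")

  reps <- refdb$representatives
  qk <- .kmers(query)
  if (length(qk) == 0L) return(NULL)
  cand <- which(vapply(reps$sequence,
                       function(s) any(.kmers(s) %in% qk), logical(1L),
                       USE.NAMES = FALSE))
  if (length(cand) == 0L) return(NULL)

  aln <- .identity_vs(reps$sequence[cand], query, "local")
  ord <- order(-aln$identity, -aln$score, reps$group_id[cand],
               reps$protein_id[cand])
  best <- ord[1L]
  if (aln$identity[best] < min_identity) return(NULL)
  hit <- data.frame(group_id = reps$group_id[cand][best],
                    representative_id = reps$protein_id[cand][best],
                    identity = aln$identity[best],
                    score = aln$score[best],
                    low_confidence = aln$identity[best] < refdb$identity_threshold,
                    stringsAsFactors = FALSE)
  class(hit) <- c("seed_hit", class(hit))
  hit
}
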