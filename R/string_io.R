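# Readers and writers for the STRING-style flat files that feed the pipeline:
# species table, NCBI-taxonomy lineage dump, orthologous-group membership
# table, group-group association score table, and protein FASTA.
#
# All readers validate fully before returning: no partially validated data
# escapes. Comment lines starting with "#" and blank lines are tolerated
# everywhere (real STRING dumps carry headers). Encoding is fixed to UTF-8.

# Read non-comment data lines together with their original line numbers.
.read_data_lines <- function(path) {
  if (!file.exists(path)) .io_error(sprintf("file not found: %s", path))
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(text = raw[keep], lineno = which(keep))
}

# Split a line on tabs if it contains any, otherwise on runs of spaces.
.split_fields <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) strsplit(line, "\t", fixed = TRUE)[[1L]]
  else strsplit(trimws(line), " +")[[1L]]
}

.parse_taxon_id <- function(x, lineno, path) {
  ok <- grepl("^[0-9]+$", x)
  if (any(!ok))
    .parse_error(sprintf("%s:%d: malformed taxon id '%s'",
                         path, lineno[which(!ok)[1L]], x[which(!ok)[1L]]))
  id <- suppressWarnings(as.integer(x))
  bad <- is.na(id) | id < 1L
  if (any(bad))
    .parse_error(sprintf("%s:%d: taxon id must be a positive integer, got '%s'",
                         path, lineno[which(bad)[1L]], x[which(bad)[1L]]))
  id
}

#' Read a species table
#'
#' Parses a STRING-style species table: one organism per line, taxon id first,
#' then the organism name (which may contain spaces). Lines beginning with
#' \code{#} are skipped.
#'
#' @param path Path to the species file.
#' @return A data frame with columns \code{taxon_id} (integer) and
#'   \code{name} (character). Taxon ids are guaranteed unique and names
#'   non-empty.
#' @examples
#' f <- tempfile()
#' writeLines(c("9606\tHomo sapiens", "562\tEscherichia coli"), f)
#' read_species(f)
#' @export
read_species <- function(path) {
  ln <- .read_data_lines(path)
  if (length(ln$text) == 0L)
    return(data.frame(taxon_id = integer(), name = character(),
                      stringsAsFactors = FALSE))
  sep <- regexpr("[ \t]", ln$text)
  if (any(sep < 0L))
    .parse_error(sprintf("%s:%d: expected '<taxon id><delim><name>'",
                         path, ln$lineno[which(sep < 0L)[1L]]))
  id <- .parse_taxon_id(substr(ln$text, 1L, sep - 1L), ln$lineno, path)
  name <- trimws(substr(ln$text, sep + 1L, nchar(ln$text)))
  if (any(name == ""))
    .validation_error(sprintf("%s:%d: empty organism name",
                              path, ln$lineno[which(name == "")[1L]]))
  if (anyDuplicated(id))
    .validation_error(sprintf("%s: duplicate taxon id %d",
                              path, id[duplicated(id)][1L]))
  data.frame(taxon_id = id, name = name, stringsAsFactors = FALSE)
}

#' Read a lineage dump
#'
#' Parses the NCBI taxonomy \code{fullnamelineage.dmp} dialect: fields
#' separated by \code{"\\t|\\t"}, records terminated by \code{"\\t|"}; the
#' third field is the semicolon-separated lineage from the root down to the
#' organism's immediate parent.
#'
#' @param path Path to the dump file.
#' @return A data frame with columns \code{taxon_id} (integer) and
#'   \code{lineage} (list of character vectors; components trimmed, empty
#'   components dropped).
#' @export
read_lineages <- function(path) {
  ln <- .read_data_lines(path)
  if (length(ln$text) == 0L) {
    out <- data.frame(taxon_id = integer(), stringsAsFactors = FALSE)
    out$lineage <- list()
    return(out)
  }
  body <- sub("\t\\|$", "", ln$text)
  fields <- strsplit(body, "\t|\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    .parse_error(sprintf("%s:%d: expected 3 fields separated by '\\t|\\t', got %d",
                         path, ln$lineno[which(nf != 3L)[1L]], nf[which(nf != 3L)[1L]]))
  id <- .parse_taxon_id(trimws(vapply(fields, `[`, "", 1L)), ln$lineno, path)
  if (anyDuplicated(id))
    .validation_error(sprintf("%s: duplicate taxon id %d in lineage dump",
                              path, id[duplicated(id)][1L]))
  lineage <- lapply(fields, function(f) {
    parts <- trimws(strsplit(f[[3L]], ";", fixed = TRUE)[[1L]])
    parts[parts != ""]
  })
  empty <- lengths(lineage) == 0L
  if (any(empty))
    .validation_error(sprintf("%s:%d: empty lineage", path,
                              ln$lineno[which(empty)[1L]]))
  out <- data.frame(taxon_id = id, stringsAsFactors = FALSE)
  out$lineage <- lineage
  out
}

#' Read an orthologous-group membership table
#'
#' Each data line maps one protein of one organism to one orthologous group
#' (COG/KOG). Two layouts are supported: \code{"string"}, two columns with a
#' combined \code{taxid.protein} identifier followed by the group id (the
#' layout of real STRING mapping dumps), and \code{"three_column"}, explicit
#' \code{taxon_id}, \code{protein_id}, \code{group_id} columns. The default
#' \code{"auto"} detects the layout from the field count of the first data
#' line.
#'
#' @param path Path to the membership file.
#' @param format One of \code{"auto"}, \code{"string"}, \code{"three_column"}.
#' @return A data frame with columns \code{group_id}, \code{taxon_id},
#'   \code{protein_id}; triples are unique and group ids match
#'   \code{COG}\\d{4} or \code{KOG}\\d{4}.
#' @export
read_memberships <- function(path, format = c("auto", "string", "three_column")) {
  format <- match.arg(format)
  ln <- .read_data_lines(path)
  if (length(ln$text) == 0L)
    return(data.frame(group_id = character(), taxon_id = integer(),
                      protein_id = character(), stringsAsFactors = FALSE))
  fields <- lapply(ln$text, .split_fields)
  nf <- lengths(fields)
  if (format == "auto") format <- if (nf[1L] == 3L) "three_column" else "string"
  want <- if (format == "three_column") 3L else 2L
  if (any(nf != want))
    .parse_error(sprintf("%s:%d: expected %d fields, got %d", path,
                         ln$lineno[which(nf != want)[1L]], want,
                         nf[which(nf != want)[1L]]))
  if (format == "three_column") {
    taxon <- .parse_taxon_id(vapply(fields, `[`, "", 1L), ln$lineno, path)
    protein <- vapply(fields, `[`, "", 2L)
    group <- vapply(fields, `[`, "", 3L)
  } else {
    combined <- vapply(fields, `[`, "", 1L)
    dot <- regexpr(".", combined, fixed = TRUE)
    if (any(dot < 0L))
      .parse_error(sprintf("%s:%d: expected 'taxid.protein' identifier", path,
                           ln$lineno[which(dot < 0L)[1L]]))
    taxon <- .parse_taxon_id(substr(combined, 1L, dot - 1L), ln$lineno, path)
    protein <- substr(combined, dot + 1L, nchar(combined))
    group <- vapply(fields, `[`, "", 2L)
  }
  bad <- !.is_group_id(group)
  if (any(bad))
    .validation_error(sprintf("%s:%d: invalid group id '%s' (expected COG/KOG + 4 digits)",
                              path, ln$lineno[which(bad)[1L]], group[which(bad)[1L]]))
  if (any(protein == ""))
    .validation_error(sprintf("%s:%d: empty protein id", path,
                              ln$lineno[which(protein == "")[1L]]))
  key <- paste(group, taxon, protein, sep = "\r")
  if (anyDuplicated(key))
    .validation_error(sprintf("%s: duplicate membership (%s)", path,
                              gsub("\r", ", ", key[duplicated(key)][1L], fixed = TRUE)))
  data.frame(group_id = group, taxon_id = taxon, protein_id = protein,
             stringsAsFactors = FALSE)
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct an association table
#'
#' An association table stores STRING-style confidence scores (integers in
#' \[0, 1000\]) for unordered pairs of orthologous groups. Lookups are
#' symmetric; self-pairs are not representable.
#'
#' @param a,b Character vectors of group ids (paired elementwise).
#' @param score Integer scores in \[0, 1000\].
#' @return An object of class \code{association_table}.
#' @seealso [read_links()], [assoc_score()]
#' @export
association_table <- function(a = character(), b = character(), score = integer()) {
  if (length(a) != length(b) || length(a) != length(score))
    .usage_error("'a', 'b' and 'score' must have equal length")
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) .validation_error(sprintf("self-pair not allowed: %s", a[a == b][1L]))
  if (any(!.is_group_id(c(a, b))))
    .validation_error("group ids must match COG/KOG + 4 digits")
  s <- suppressWarnings(as.numeric(score))
  if (any(is.na(s)) || any(s != floor(s)) || any(s < 0) || any(s > 1000))
    .validation_error("scores must be integers in [0, 1000]")
  s <- as.integer(s)
  key <- .pair_key(a, b)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    ref <- stats::setNames(s[first], key[first])
    if (any(ref[key] != s))
      .validation_error("conflicting duplicate scores for a group pair")
    key <- key[first]; s <- s[first]
  }
  lo <- vapply(strsplit(key, "\r", fixed = TRUE), `[`, "", 1L)
  hi <- vapply(strsplit(key, "\r", fixed = TRUE), `[`, "", 2L)
  ord <- order(lo, hi)
  structure(list(pairs = data.frame(a = lo[ord], b = hi[ord], score = s[ord],
                                    stringsAsFactors = FALSE),
                 index = stats::setNames(s[ord], key[ord])),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table: %d pairs, %d groups>\n",
              nrow(x$pairs), length(assoc_groups(x))))
  invisible(x)
}

#' Look up a symmetric association score
#'
#' @param table An \code{association_table}.
#' @param a,b Group ids (vectors recycle elementwise).
#' @return Integer score(s); \code{NA} for unrecorded pairs.
#' @export
assoc_score <- function(table, a, b) {
  stopifnot(inherits(table, "association_table"))
  unname(table$index[.pair_key(as.character(a), as.character(b))])
}

#' Group ids present in an association table
#' @param table An \code{association_table}.
#' @return Sorted character vector of group ids.
#' @export
assoc_groups <- function(table) {
  stopifnot(inherits(table, "association_table"))
  sort(unique(c(table$pairs$a, table$pairs$b)))
}

#' Read a group-group association score table
#'
#' Each data line carries two group ids and an integer score in \[0, 1000\].
#' The table is symmetric: if both orders of a pair appear they must carry
#' the same score, otherwise a validation error is raised.
#'
#' @param path Path to the links file.
#' @return An \code{association_table}.
#' @export
read_links <- function(path) {
  ln <- .read_data_lines(path)
  if (length(ln$text) == 0L) return(association_table())
  fields <- lapply(ln$text, .split_fields)
  nf <- lengths(fields)
  if (any(nf != 3L))
    .parse_error(sprintf("%s:%d: expected 'group_a group_b score'", path,
                         ln$lineno[which(nf != 3L)[1L]]))
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  sc <- vapply(fields, `[`, "", 3L)
  if (any(!grepl("^[0-9]+$", sc)))
    .validation_error(sprintf("%s:%d: malformed score '%s'", path,
                              ln$lineno[which(!grepl("^[0-9]+$", sc))[1L]],
                              sc[which(!grepl("^[0-9]+$", sc))[1L]]))
  withCallingHandlers(
    association_table(a, b, as.integer(sc)),
    phylocog_validation_error = function(e) {
      .validation_error(sprintf("%s: %s", path, conditionMessage(e)))
    })
}

# amino-acid alphabet: the 20 standard residues plus X (unknown)
.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]

.validate_protein <- function(seq, id) {
  if (length(seq) == 0L) return(invisible(TRUE))
  if (any(!nzchar(seq)))
    .validation_error(sprintf("empty sequence for record '%s'", id[!nzchar(seq)][1L]))
  chars <- strsplit(seq, "")
  ok <- vapply(chars, function(ch) all(ch %in% .aa_alphabet), logical(1L))
  if (any(!ok)) {
    i <- which(!ok)[1L]
    badch <- setdiff(chars[[i]], .aa_alphabet)[1L]
    .validation_error(sprintf("record '%s': character '%s' outside the amino-acid alphabet",
                              id[i], badch))
  }
  invisible(TRUE)
}

#' Read protein sequences from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet plus X.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .io_error(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(), character()))
  id <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  seq <- toupper(as.character(set))
  .validate_protein(seq, id)
  stats::setNames(seq, id)
}

#' Write protein sequences to FASTA
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  .validate_protein(toupper(unname(sequences)), names(sequences))
  set <- Biostrings::BStringSet(toupper(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

.check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) .io_error(sprintf("directory does not exist: %s", dir))
  invisible(TRUE)
}

#' Write a species table
#' @param species Data frame with columns \code{taxon_id}, \code{name}.
#' @param path Output path.
#' @return The path, invisibly. Round-trips through [read_species()].
#' @export
write_species <- function(species, path) {
  .check_writable(path)
  if (anyDuplicated(species$taxon_id)) .validation_error("duplicate taxon ids")
  if (any(!nzchar(trimws(species$name)))) .validation_error("empty organism name")
  writeLines(paste(species$taxon_id, species$name, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Write a lineage dump
#' @param lineages Data frame with columns \code{taxon_id} and list column
#'   \code{lineage}, as returned by [read_lineages()].
#' @param path Output path.
#' @return The path, invisibly. Round-trips through [read_lineages()].
#' @export
write_lineages <- function(lineages, path) {
  .check_writable(path)
  last <- vapply(lineages$lineage, function(l) l[[length(l)]], "")
  lines <- paste0(lineages$taxon_id, "\t|\t", last, "\t|\t",
                  vapply(lineages$lineage, paste, "", collapse = "; "), "\t|")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write an orthologous-group membership table
#' @param memberships Data frame with columns \code{group_id},
#'   \code{taxon_id}, \code{protein_id}.
#' @param path Output path.
#' @param format \code{"string"} (combined \code{taxid.protein} id) or
#'   \code{"three_column"}.
#' @return The path, invisibly. Round-trips through [read_memberships()].
#' @export
write_memberships <- function(memberships, path,
                              format = c("string", "three_column")) {
  format <- match.arg(format)
  .check_writable(path)
  if (nrow(memberships) == 0L) { writeLines(character(), path); return(invisible(path)) }
  if (any(!.is_group_id(memberships$group_id)))
    .validation_error("invalid group id in memberships")
  lines <- if (format == "three_column")
    paste(memberships$taxon_id, memberships$protein_id, memberships$group_id, sep = "\t")
  else
    paste0(memberships$taxon_id, ".", memberships$protein_id, "\t", memberships$group_id)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a group-group association score table
#' @param links An \code{association_table}.
#' @param path Output path.
#' @return The path, invisibly. Round-trips through [read_links()].
#' @export
write_links <- function(links, path) {
  stopifnot(inherits(links, "association_table"))
  .check_writable(path)
  writeLines(paste(links$pairs$a, links$pairs$b, links$pairs$score, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}
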