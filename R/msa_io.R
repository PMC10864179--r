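# MSA input/output: HH-suite A3M dialect and aligned FASTA, the 22-state
# integer encoding, and UniProt-style species annotation parsing.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The 22-state alignment alphabet
#'
#' States 0-19 are the twenty canonical amino acids in alphabetical
#' one-letter order (`A C D E F G H I K L M N P Q R S T V W Y`), state 20 is
#' the unknown / nonstandard residue state (X, and also B, Z, J, U, O or any
#' unrecognized letter), and state 21 is the gap state. This fixed order
#' makes Potts coupling and frequency indices reproducible.
#'
#' @return Named integer vector mapping each symbol to its state 0..21.
#' @export
#' @examples
#' alphabet22()[c("A", "X", "-")]
alphabet22 <- function() {
  setNames(0:21, c(AA20, "X", "-"))
}

chars_to_states <- function(ch) {
  st <- match(ch, AA20) - 1L
  st[ch == "-" | ch == "."] <- 21L
  st[is.na(st)] <- 20L
  as.integer(st)
}

states_to_chars <- function(st) c(AA20, "X", "-")[st + 1L]

# Match columns are the uppercase letters and '-'; lowercase letters are A3M
# insertions and '.' is an alignment placeholder, neither occupies a query
# column.
match_seq <- function(s) gsub("[a-z.]", "", s)

n_match_cols <- function(s) nchar(match_seq(s))

#' Construct an MSA object
#'
#' An `msa` is an ordered collection of aligned sequences over the query's
#' match-column coordinate system. The first record is always the query: it
#' must be gapless and defines the alignment length `L`. Every other record
#' must present exactly `L` match columns (uppercase residues or `-`);
#' lowercase letters are insertions outside the query coordinate system.
#'
#' @param id character vector of record identifiers (first is the query).
#' @param seq character vector of aligned sequences (A3M dialect).
#' @param desc full header descriptions; defaults to the ids.
#' @param species optional character vector of species keys (`NA` = absent).
#' @return An object of class `msa` with fields `id`, `desc`, `seq`,
#'   `species`, `L` (query length) and `N` (number of rows).
#' @export
#' @examples
#' m <- msa(c("q", "h1"), c("ACDE", "AC-E"))
#' m$L
msa <- function(id, seq, desc = id, species = NULL) {
  if (length(id) == 0L || length(seq) == 0L) {
    format_error("an MSA needs at least one record (the query)")
  }
  if (length(id) != length(seq)) {
    format_error("'id' and 'seq' must have equal length")
  }
  id <- as.character(id)
  seq <- as.character(seq)
  desc <- as.character(desc)
  if (any(!nzchar(id))) format_error("record ids must be non-empty")
  if (any(!nzchar(seq))) {
    format_error(sprintf("record '%s' has an empty sequence",
                         id[which(!nzchar(seq))[1]]))
  }
  qmatch <- match_seq(seq[1])
  if (grepl("-", qmatch, fixed = TRUE)) {
    format_error(sprintf("query record '%s' must be gapless", id[1]))
  }
  L <- nchar(qmatch)
  if (L < 1L) format_error("query defines zero match columns")
  mc <- vapply(seq, n_match_cols, integer(1), USE.NAMES = FALSE)
  if (any(mc != L)) {
    bad <- which(mc != L)[1]
    format_error(sprintf(
      "record '%s' has %d match columns; expected %d (ragged alignment)",
      id[bad], mc[bad], L))
  }
  if (is.null(species)) species <- rep(NA_character_, length(id))
  species <- as.character(species)
  if (length(species) != length(id)) {
    format_error("'species' must match the number of records")
  }
  structure(
    list(id = id, desc = desc, seq = seq, species = species,
         L = L, N = length(id)),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequence(s), L = %d match columns\n", x$N, x$L))
  cat(sprintf("query: %s\n", x$id[1]))
  n_show <- min(x$N, 5L)
  for (i in seq_len(n_show)) {
    s <- x$seq[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-12s %s\n", x$id[i], s))
  }
  if (x$N > n_show) cat(sprintf("  ... and %d more\n", x$N - n_show))
  invisible(x)
}

is_msa <- function(x) inherits(x, "msa")

# Normalize an input (file path, connection, or literal text) to lines.
read_input_lines <- function(input) {
  if (inherits(input, "connection")) return(readLines(input, warn = FALSE))
  if (!is.character(input)) io_error("input must be a path, connection or text")
  if (length(input) == 1L && !nzchar(input)) return(character())
  if (length(input) > 1L || any(grepl("\n", input, fixed = TRUE))) {
    return(unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE))
  }
  if (startsWith(input, ">")) {
    return(unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE))
  }
  if (!file.exists(input)) io_error(sprintf("cannot open input '%s'", input))
  readLines(input, warn = FALSE)
}

parse_fasta_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) format_error("empty input: no FASTA records found")
  hdr <- grepl("^>", lines)
  if (!hdr[1]) format_error("input does not start with a FASTA header")
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("[ \t]", "", paste0(x, collapse = "")),
                 character(1))
  # records with a header but no sequence lines
  if (length(seqs) != sum(hdr)) {
    present <- as.integer(names(seqs))
    missing <- setdiff(seq_len(sum(hdr)), present)
    format_error(sprintf("record '%s' has no sequence lines",
                         sub("\\s.*", "", headers[missing[1]])))
  }
  list(headers = trimws(headers), seqs = unname(seqs))
}

#' Read an MSA in A3M format
#'
#' Parses the HH-suite A3M dialect: the first record is the query, uppercase
#' letters and `-` are query match columns, lowercase letters are insertions,
#' and `.` placeholders are dropped. Species keys are extracted from the
#' headers with [parse_species()].
#'
#' @param input file path, connection, or character text of the A3M content.
#' @param species_mode passed to [parse_species()] (`"auto"`, `"taxid"` or
#'   `"name"`).
#' @return An [msa] object.
#' @export
#' @examples
#' read_a3m(">q\nACDE\n>h1\nAC-E\n")
read_a3m <- function(input, species_mode = c("auto", "taxid", "name")) {
  species_mode <- match.arg(species_mode)
  rec <- parse_fasta_lines(read_input_lines(input))
  ids <- sub("\\s.*", "", rec$headers)
  msa(id = ids, seq = rec$seqs, desc = rec$headers,
      species = parse_species(rec$headers, mode = species_mode))
}

#' Read an MSA in aligned-FASTA format
#'
#' Accepted when all rows have equal length and the query (first record)
#' carries no gaps; every column is then a query match column.
#'
#' @inheritParams read_a3m
#' @return An [msa] object.
#' @export
read_aligned_fasta <- function(input, species_mode = c("auto", "taxid", "name")) {
  species_mode <- match.arg(species_mode)
  rec <- parse_fasta_lines(read_input_lines(input))
  len <- nchar(rec$seqs)
  if (length(unique(len)) != 1L) {
    bad <- which(len != len[1])[1]
    format_error(sprintf(
      "aligned FASTA rows must have equal length; record '%s' has %d columns, expected %d",
      sub("\\s.*", "", rec$headers[bad]), len[bad], len[1]))
  }
  ids <- sub("\\s.*", "", rec$headers)
  msa(id = ids, seq = toupper(rec$seqs), desc = rec$headers,
      species = parse_species(rec$headers, mode = species_mode))
}

#' Read an MSA, inferring the format
#'
#' @param input file path (extension `.a3m` vs `.afa`/`.fa`/`.fasta` decides
#'   the dialect), connection or text.
#' @param format `"auto"`, `"a3m"` or `"afa"`.
#' @param ... passed to the format-specific reader.
#' @return An [msa] object.
#' @export
read_msa <- function(input, format = c("auto", "a3m", "afa"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (is.character(input) && length(input) == 1L &&
                  grepl("\\.(afa|fa|fasta)$", input, ignore.case = TRUE)) {
      "afa"
    } else {
      "a3m"
    }
  }
  switch(format, a3m = read_a3m(input, ...), afa = read_aligned_fasta(input, ...))
}

#' Write an MSA in A3M format
#'
#' Round-trip property: `read_a3m(write_a3m(m))` reproduces ids, order and
#' residues.
#'
#' @param x an [msa] object.
#' @param file optional path; when `NULL` the text is returned.
#' @return The A3M text, invisibly when written to a file.
#' @export
write_a3m <- function(x, file = NULL) {
  stopifnot(is_msa(x))
  hdr <- ifelse(nzchar(x$desc), x$desc, x$id)
  txt <- paste0(">", hdr, "\n", x$seq, collapse = "\n")
  txt <- paste0(txt, "\n")
  if (is.null(file)) return(txt)
  writeLines(sub("\n$", "", txt), file)
  invisible(txt)
}

#' Write an MSA in aligned-FASTA format (match columns only)
#'
#' Insertions (lowercase) fall outside the query coordinate system and are
#' dropped, so every row is written with exactly `L` columns.
#'
#' @inheritParams write_a3m
#' @return The FASTA text, invisibly when written to a file.
#' @export
write_aligned_fasta <- function(x, file = NULL) {
  stopifnot(is_msa(x))
  hdr <- ifelse(nzchar(x$desc), x$desc, x$id)
  txt <- paste0(">", hdr, "\n", vapply(x$seq, match_seq, character(1)),
                collapse = "\n")
  txt <- paste0(txt, "\n")
  if (is.null(file)) return(txt)
  writeLines(sub("\n$", "", txt), file)
  invisible(txt)
}

#' Encode an MSA as an N x L integer state matrix
#'
#' Maps every match column onto the 22-state alphabet ([alphabet22()]):
#' insertions are dropped, gaps map to state 21 and unrecognized letters
#' (B, Z, J, U, O, ...) map to the unknown state 20.
#'
#' @param x an [msa] object.
#' @return Integer matrix (N rows, L columns) with entries in 0..21 and the
#'   record ids as row names.
#' @export
to_match_matrix <- function(x) {
  stopifnot(is_msa(x))
  m <- matrix(0L, nrow = x$N, ncol = x$L,
              dimnames = list(x$id, NULL))
  for (n in seq_len(x$N)) {
    m[n, ] <- chars_to_states(strsplit(match_seq(x$seq[n]), "")[[1]])
  }
  m
}

# Character match-column matrix (uppercase residues and '-'); internal.
match_char_matrix <- function(x) {
  stopifnot(is_msa(x))
  matrix(unlist(strsplit(vapply(x$seq, match_seq, character(1)), ""),
                use.names = FALSE),
         nrow = x$N, ncol = x$L, byrow = TRUE,
         dimnames = list(x$id, NULL))
}

#' Extract a species key from a UniProt-style FASTA header
#'
#' In `auto` mode the numeric `OX=` taxon identifier takes precedence, the
#' `OS=` organism name is the fallback, and `NA` is returned when neither is
#' present (e.g. metagenome-derived sequences carry no species annotation and
#' are therefore unlinkable). Comparison downstream is exact string match
#' after whitespace trimming.
#'
#' @param header character vector of FASTA header lines (without `>`).
#' @param mode `"auto"` (OX then OS), `"taxid"` (OX only) or `"name"`
#'   (OS only).
#' @return Character vector of species keys; `NA` where absent.
#' @export
#' @examples
#' parse_species("sp|P12345|NAME_HUMAN Desc OS=Homo sapiens OX=9606")
#' parse_species("tr|Q99999|X OS=Mus musculus")
#' parse_species("metagenome_contig_17")
parse_species <- function(header, mode = c("auto", "taxid", "name")) {
  mode <- match.arg(mode)
  header <- as.character(header)
  ox <- rep(NA_character_, length(header))
  hit <- regexpr("OX=([0-9]+)", header)
  has <- hit > 0
  ox[has] <- sub("^OX=", "", regmatches(header, hit)[seq_len(sum(has))])
  os <- rep(NA_character_, length(header))
  m <- regexec("OS=(.*?)(?:\\s+[A-Z]{2}=.*)?$", header, perl = TRUE)
  mm <- regmatches(header, m)
  got <- lengths(mm) == 2L
  os[got] <- trimws(vapply(mm[got], `[`, character(1), 2L))
  os[!is.na(os) & !nzchar(os)] <- NA_character_
  switch(mode,
         taxid = ox,
         name = os,
         auto = ifelse(is.na(ox), os, ox))
}
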