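#' @useDynLib mirhunt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Normalize a nucleotide sequence to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Ambiguity codes are preserved; downstream
#' filters reject candidates that contain them. Idempotent.
#'
#' @param x character vector of sequences.
#' @return character vector over the RNA alphabet.
#' @export
normalize_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences.
#' @return reverse complements, same length.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' GC and A+U content (percent)
#'
#' Percentages are computed over unambiguous A/C/G/U letters only.
#'
#' @param x a single sequence.
#' @return named numeric vector with `gc` and `au` in percent.
#' @export
base_content <- function(x) {
  ch <- seq_chars(normalize_rna(x))
  ch <- ch[ch %in% c("A", "C", "G", "U")]
  if (length(ch) == 0L) return(c(gc = NA_real_, au = NA_real_))
  gc <- 100 * sum(ch %in% c("G", "C")) / length(ch)
  c(gc = gc, au = 100 - gc)
}

has_ambiguity <- function(x) {
  grepl("[^ACGU]", normalize_rna(x))
}

#' Read a FASTA file into a table of sequence records
#'
#' Sequences are uppercased and stored in the RNA alphabet (T converted to
#' U); the original alphabet is recorded per record. Wrapped sequence lines
#' are concatenated.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` detects DNA (contains T) vs RNA per record;
#'   `"dna"`/`"rna"` force the recorded origin. Either way the stored
#'   sequence is RNA.
#' @return data.frame with columns `id`, `description`, `sequence`,
#'   `alphabet_origin`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA header at line ", first, " of ", path,
         ": expected '>'")
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- vapply(seqs, function(s)
    any(!seq_chars(s) %in% c(IUPAC_NT, "-")), logical(1))
  if (any(bad)) {
    stop("non-IUPAC letters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  origin <- switch(alphabet,
    dna = rep("dna", length(seqs)),
    rna = rep("rna", length(seqs)),
    auto = ifelse(grepl("T", seqs, fixed = TRUE), "dna", "rna"))
  data.frame(id = unname(ids), description = unname(desc),
             sequence = unname(normalize_rna(seqs)),
             alphabet_origin = unname(origin),
             stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records data.frame as returned by [read_fasta()], or a named
#'   character vector of sequences.
#' @param path output path.
#' @param wrap positive line width for sequence wrapping (default 60).
#' @param as `"rna"` writes sequences as stored; `"dna"` converts U to T.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60, as = c("rna", "dna")) {
  as <- match.arg(as)
  if (is.character(records)) {
    if (is.null(names(records))) stop("records vector must be named")
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0L) stop("no records to write")
  if (!is.numeric(wrap) || length(wrap) != 1L || wrap < 1) {
    stop("wrap must be a positive integer")
  }
  seqs <- records$sequence
  if (as == "dna") seqs <- chartr("U", "T", seqs)
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description),
                    records$id)
  set <- Biostrings::BStringSet(setNames(seqs, headers))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = as.integer(wrap))
  invisible(path)
}

mirna_family <- function(name) {
  # "osa-MIR169a" -> "MIR169"; "sim-miR444d-5p" -> "MIR444"
  core <- sub("^[A-Za-z]{3,4}-", "", name)
  core <- sub("^miR", "MIR", core)
  m <- regmatches(core, regexpr("^MIR[0-9]+", core))
  if (length(m) == 0L || !nzchar(m)) return(NA_character_)
  m
}

mature_to_precursor_name <- function(name) {
  # "osa-miR169a-5p" -> "osa-MIR169a"
  x <- sub("-(5p|3p)$", "", name)
  x <- sub("\\.[0-9]+$", "", x)
  sub("-miR", "-MIR", x, fixed = TRUE)
}

#' Pair precursor and mature FASTA files into a reference miRNA set
#'
#' Matures are matched to precursors by the miRBase-style naming convention
#' (`miR` vs `MIR`, optional `-5p`/`-3p` suffixes). A mature whose sequence
#' is not a substring of its precursor is kept but flagged detached, with a
#' warning; likewise a mature with no matching precursor.
#'
#' @param precursor_fasta,mature_fasta FASTA paths, or record data.frames as
#'   returned by [read_fasta()].
#' @return list of `reference_mirna` objects: `name`, `family`,
#'   `species_code`, `precursor` (sequence), `matures` (named character
#'   vector), `detached` (named logical vector).
#' @export
parse_reference_set <- function(precursor_fasta, mature_fasta) {
  prec <- if (is.character(precursor_fasta)) read_fasta(precursor_fasta)
          else precursor_fasta
  mat <- if (is.character(mature_fasta)) read_fasta(mature_fasta)
         else mature_fasta
  refs <- lapply(seq_len(nrow(prec)), function(i) {
    name <- prec$id[i]
    structure(list(
      name = name,
      family = mirna_family(name),
      species_code = sub("-.*$", "", name),
      precursor = prec$sequence[i],
      matures = character(0),
      detached = logical(0)
    ), class = "reference_mirna")
  })
  names(refs) <- prec$id
  for (i in seq_len(nrow(mat))) {
    target <- mature_to_precursor_name(mat$id[i])
    hit <- if (target %in% names(refs)) target else {
      cand <- names(refs)[startsWith(target, names(refs))]
      if (length(cand)) cand[which.max(nchar(cand))] else NA_character_
    }
    if (is.na(hit)) {
      warning("mature ", mat$id[i], " has no matching precursor; kept detached")
      ref <- structure(list(
        name = target, family = mirna_family(mat$id[i]),
        species_code = sub("-.*$", "", mat$id[i]),
        precursor = "", matures = setNames(mat$sequence[i], mat$id[i]),
        detached = setNames(TRUE, mat$id[i])
      ), class = "reference_mirna")
      refs[[target]] <- ref
      next
    }
    det <- !grepl(mat$sequence[i], refs[[hit]]$precursor, fixed = TRUE)
    if (det) warning("mature ", mat$id[i],
                     " is not a substring of precursor ", hit,
                     "; flagged detached")
    refs[[hit]]$matures <- c(refs[[hit]]$matures,
                             setNames(mat$sequence[i], mat$id[i]))
    refs[[hit]]$detached <- c(refs[[hit]]$detached,
                              setNames(det, mat$id[i]))
  }
  unname(refs)
}

#' @export
print.reference_mirna <- function(x, ...) {
  cat("<reference_mirna> ", x$name, " (", x$family, "), ",
      nchar(x$precursor), " nt precursor, ", length(x$matures),
      " mature(s)\n", sep = "")
  invisible(x)
}
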