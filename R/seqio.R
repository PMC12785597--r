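#' Read template sequences from FASTA
#'
#' Reads a multi-record FASTA of candidate templates. Residues are
#' normalized (lowercase to uppercase, `U` to `T`) and validated against the
#' IUPAC nucleotide alphabet; gap characters are rejected because the
#' pipeline consumes unaligned sequences. Record ids must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with `mcols()`
#'   columns `id`, `description` (header text after the id, possibly empty)
#'   and `species` (first token of the description, falling back to the id).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1 Cervus_nippon", "acgtacgtacgu"), f)
#' tt <- readTemplates(f)
#' mcols(tt)$species
#' @export
readTemplates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("no templates in ", path, call. = FALSE)
  raw <- tryCatch(readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!length(raw)) stop("no templates in ", path, call. = FALSE)
  headers <- names(raw)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    stop("malformed FASTA header (empty id) in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(sQuote(unique(dup)), collapse = ", "), call. = FALSE)
  }
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  res <- .normalizeResidues(as.character(raw))
  for (i in seq_along(res)) .validateResidues(res[[i]], ids[[i]])
  out <- DNAStringSet(res)
  names(out) <- ids
  mcols(out) <- DataFrame(
    id = ids, description = desc,
    species = ifelse(nzchar(desc),
                     vapply(strsplit(desc, "\\s+"), `[`, character(1), 1L),
                     ids))
  out
}

#' Write template sequences to FASTA
#'
#' Headers are `id description` when a description is present in `mcols()`,
#' otherwise the bare id. Round-trips with [readTemplates()] on normalized
#' input.
#'
#' @param x A [Biostrings::DNAStringSet] as returned by [readTemplates()] or
#'   the synthetic generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTemplates <- function(x, path) {
  stopifnot(is(x, "DNAStringSet"))
  out <- x
  mc <- mcols(x)
  if (!is.null(mc) && !is.null(mc$description)) {
    names(out) <- ifelse(nzchar(mc$description),
                         paste(names(x), mc$description), names(x))
  }
  writeXStringSet(out, filepath = path)
  invisible(path)
}

#' Read a primer pair
#'
#' Accepts either a two-record FASTA (first record = forward, second =
#' reverse) or a two-row TSV with columns `name` and `sequence`. Sequences
#' are normalized like templates; primers shorter than 10 nt are rejected.
#'
#' @param path Path to the primer file.
#' @return A list with elements `fwd` and `rev`, each a [Primer-class].
#' @export
readPrimers <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), ">")) {
    seqs <- readBStringSet(path)
    nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    sq <- as.character(seqs)
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (!all(c("name", "sequence") %in% names(tab))) {
      stop("primer TSV needs columns 'name' and 'sequence': ", path,
           call. = FALSE)
    }
    nm <- tab$name
    sq <- tab$sequence
  }
  if (length(nm) != 2L) {
    stop("expected exactly 2 primers (forward, reverse) in ", path,
         ", found ", length(nm), call. = FALSE)
  }
  list(fwd = primer(nm[[1L]], sq[[1L]]), rev = primer(nm[[2L]], sq[[2L]]))
}

#' The sika deer COI authentication primer pair
#'
#' The species-specific primer pair targeting the mitochondrial cytochrome c
#' oxidase subunit I (COI) gene of sika deer (*Cervus nippon*), used
#' throughout the examples: on the target sequence the pair delimits a
#' 526 bp amplicon, while congeners carry mismatches concentrated at the
#' primer 3' ends.
#'
#' @return A list with elements `fwd` and `rev` ([Primer-class] objects).
#' @examples
#' sikaCoiPrimers()
#' @export
sikaCoiPrimers <- function() {
  list(fwd = primer("COI-F", "ACACCCTAATCAACTGGC"),
       rev = primer("COI-R", "AAGAAAGAAGGAGGGAGG"))
}
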