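#' Alu reference element
#'
#' Bundle an Alu element's core sequence with its annotated intervals: the
#' left-arm and right-arm SRP9/14 binding stem-loop regions and the core
#' span. All intervals are 0-based half-open `[start, end)` in element
#' coordinates.
#'
#' @param id Element identifier (e.g. `"AluSx_syn"`).
#' @param sequence DNA string over A/C/G/T, typically 280-300 bases.
#' @param srp_left,srp_right Integer length-2 vectors `c(start, end)` for the
#'   left-arm and right-arm SRP binding regions; `srp_left` must precede
#'   `srp_right`.
#' @param core Interval of the core element span (defaults to the whole
#'   sequence).
#' @return An object of class `alu_reference`: a list with fields `id`,
#'   `sequence`, `length`, `srp_left`, `srp_right`, `core`.
#' @export
alu_reference <- function(id, sequence,
                          srp_left, srp_right,
                          core = c(0L, nchar(sequence))) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence))
    stop("reference sequence must contain only A/C/G/T")
  L <- nchar(sequence)
  chk <- function(iv, name) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] < 0L || iv[2] > L || iv[1] >= iv[2])
      stop(sprintf("interval '%s' must be 0-based half-open within [0, %d)",
                   name, L))
    iv
  }
  srp_left <- chk(srp_left, "srp_left")
  srp_right <- chk(srp_right, "srp_right")
  core <- chk(core, "core")
  if (srp_left[2] > srp_right[1])
    stop("srp_left must precede srp_right")
  structure(list(id = as.character(id), sequence = sequence, length = L,
                 srp_left = srp_left, srp_right = srp_right, core = core),
            class = "alu_reference")
}

#' @export
print.alu_reference <- function(x, ...) {
  cat(sprintf("<alu_reference> %s, %d bp; SRP left [%d,%d), right [%d,%d)\n",
              x$id, x$length, x$srp_left[1], x$srp_left[2],
              x$srp_right[1], x$srp_right[2]))
  invisible(x)
}

#' Positions falling in the SRP binding regions
#'
#' @param reference An [alu_reference()].
#' @return Integer vector of 0-based positions in either SRP interval.
#' @export
srp_positions <- function(reference) {
  c(seq.int(reference$srp_left[1], reference$srp_left[2] - 1L),
    seq.int(reference$srp_right[1], reference$srp_right[2] - 1L))
}

#' Test which 0-based positions fall in an interval set
#' @param pos Integer positions (0-based).
#' @param intervals A list of `c(start, end)` half-open intervals (or a single
#'   one).
#' @return Logical vector.
#' @export
in_intervals <- function(pos, intervals) {
  if (is.numeric(intervals)) intervals <- list(intervals)
  out <- rep(FALSE, length(pos))
  for (iv in intervals) out <- out | (pos >= iv[1] & pos < iv[2])
  out
}

#' Built-in synthetic Alu-like reference
#'
#' A deterministic 290-bp synthetic stand-in for an AluS-family element,
#' generated from a fixed pseudo-random stream (it is not a genomic Alu
#' sequence). SRP binding intervals are placed near the 5' end of each arm,
#' mirroring the bipartite left/right-arm stem-loop layout of Alu RNA, with a
#' middle A-stretch separating the arms.
#'
#' @param id Identifier for the element.
#' @param seed Fixed stream seed; distinct seeds give distinct elements with
#'   the same annotation layout.
#' @return An [alu_reference()].
#' @export
synthetic_alu_reference <- function(id = "AluSyn1", seed = 20240517L) {
  # fixed stream so the element is identical across sessions
  local_rng(seed)
  bases <- c("A", "C", "G", "T")
  left <- paste(sample(bases, 120, replace = TRUE, prob = c(.24, .28, .28, .20)),
                collapse = "")
  mid <- strrep("A", 18)
  right <- paste(sample(bases, 152, replace = TRUE, prob = c(.24, .28, .28, .20)),
                 collapse = "")
  seqc <- paste0(left, mid, right)
  alu_reference(id, seqc,
                srp_left = c(15L, 55L),
                srp_right = c(160L, 200L),
                core = c(0L, nchar(seqc)))
}

#' Read Alu references from FASTA plus a BED-like region table
#'
#' @param fasta Path to a FASTA file (one record per element). Uses
#'   `Biostrings` when available, otherwise a plain-text reader.
#' @param regions Path to a BED-like TSV with columns `id`, `start`, `end`,
#'   `name`, where `name` is one of `srp_left`, `srp_right`, `core`
#'   (0-based half-open coordinates).
#' @return Named list of [alu_reference()] objects.
#' @export
read_alu_references <- function(fasta, regions) {
  seqs <- read_fasta(fasta)
  reg <- read.table(regions, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("id", "start", "end", "name")
  if (!all(need %in% names(reg)))
    stop("regions table must have columns id, start, end, name")
  out <- list()
  for (nm in names(seqs)) {
    r <- reg[reg$id == nm, , drop = FALSE]
    iv <- function(what, default = NULL) {
      i <- which(r$name == what)
      if (length(i) == 0) {
        if (is.null(default)) stop(sprintf("missing region '%s' for %s", what, nm))
        default
      } else c(r$start[i[1]], r$end[i[1]])
    }
    out[[nm]] <- alu_reference(nm, seqs[[nm]],
                               srp_left = iv("srp_left"),
                               srp_right = iv("srp_right"),
                               core = iv("core", c(0L, nchar(seqs[[nm]]))))
  }
  out
}

# Minimal FASTA read/write; Biostrings is preferred when installed so the
# standard toolchain handles the format.
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  starts <- idx + 1L
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i)
    paste(lines[starts[i]:ends[i]], collapse = ""), character(1))
  setNames(toupper(gsub("\\s", "", seqs)), ids)
}

write_fasta <- function(seqs, path, width = 70L) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(unlist(seqs))
    names(x) <- names(seqs)
    Biostrings::writeXStringSet(x, path, width = width)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Scoped RNG helper: returns nothing useful, but installs a locally seeded
# generator state and restores the caller's state when the calling frame
# exits. Keeps simulator determinism independent of ambient RNG use.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  defer <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  # embed the closure itself in the registered call so it resolves anywhere
  do.call(on.exit, list(as.call(list(defer)), add = TRUE), envir = envir)
  invisible(seed)
}
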