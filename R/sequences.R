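#' Monomer alphabet
#'
#' The model reduces a polypeptide to four monomer types: `"P"` (neutral,
#' purely repulsive), `"H"` (cohesive), `"+"` (positively charged) and `"-"`
#' (negatively charged).
#'
#' @return Character vector of the four monomer labels.
#' @export
monomer_alphabet <- function() c("P", "H", "+", "-")

#' Construct a coarse-grained sequence
#'
#' @param labels Character vector of monomer labels, each one of
#'   `monomer_alphabet()`.
#' @param name Optional sequence name.
#' @return A `cg_sequence`: a character vector of monomer labels with a
#'   `name` attribute.
#' @examples
#' cg_sequence(c("H", "P", "H", "P"), name = "hp2")
#' @export
cg_sequence <- function(labels, name = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), monomer_alphabet())
  if (length(bad) > 0) {
    stop("unknown monomer label(s): ", paste(bad, collapse = ", "))
  }
  structure(labels, class = "cg_sequence", name = name %||% "sequence")
}

#' @export
print.cg_sequence <- function(x, ...) {
  cat("<cg_sequence> ", attr(x, "name"), " (N = ", length(x), ")\n", sep = "")
  s <- paste(unclass(x), collapse = "")
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat(" ", s, "\n")
  invisible(x)
}

seq_name <- function(seq) attr(seq, "name") %||% "sequence"

#' Parse a sequence given in repeat notation
#'
#' Expands strings such as `"(HP)30"` or `"PP(HHHHPPPP)7HH"` into a
#' [cg_sequence()]. The grammar allows literal monomer letters and one level
#' of parenthesised groups; a positive integer count applies to the
#' immediately preceding group or letter, and whitespace is ignored.
#'
#' @param spec Character scalar in repeat notation.
#' @param name Optional name; defaults to the spec string itself.
#' @return A [cg_sequence()].
#' @examples
#' parse_sequence("(HP)30")      # 60-mer alternating H,P
#' parse_sequence("(HPP)33H")    # 100-mer with cohesive ends
#' @export
parse_sequence <- function(spec, name = NULL) {
  stopifnot(is.character(spec), length(spec) == 1)
  s <- gsub("[[:space:]]", "", spec)
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  read_count <- function(i) {
    j <- i
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    if (j == i) return(list(count = 1L, nxt = i))
    cnt <- as.integer(paste(chars[i:(j - 1L)], collapse = ""))
    list(count = cnt, nxt = j)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") {
        if (chars[j] == "(") stop("nested parentheses at position ", j, " in '", spec, "'")
        j <- j + 1L
      }
      if (j > n) stop("unbalanced parentheses in '", spec, "'")
      grp <- chars[(i + 1L):(j - 1L)]
      if (length(grp) == 0 || j == i + 1L) stop("empty group in '", spec, "'")
      bad <- setdiff(unique(grp), monomer_alphabet())
      if (length(bad) > 0) stop("unknown letter(s) '", paste(bad, collapse = ""), "' in '", spec, "'")
      rc <- read_count(j + 1L)
      if (rc$count < 1L) stop("non-positive repeat count after group in '", spec, "'")
      out <- c(out, rep(grp, times = rc$count))
      i <- rc$nxt
    } else if (ch == ")") {
      stop("unbalanced parentheses in '", spec, "'")
    } else if (ch %in% monomer_alphabet()) {
      rc <- read_count(i + 1L)
      if (rc$count < 1L) stop("non-positive repeat count after '", ch, "' in '", spec, "'")
      out <- c(out, rep(ch, rc$count))
      i <- rc$nxt
    } else {
      stop("unknown token '", ch, "' at position ", i, " in '", spec, "'")
    }
  }
  if (length(out) == 0) stop("empty sequence spec '", spec, "'")
  cg_sequence(out, name = name %||% spec)
}

#' Coerce to a cg_sequence
#'
#' Character scalars are interpreted as repeat notation and parsed;
#' character vectors of single letters are taken as monomer labels.
#'
#' @param x A `cg_sequence`, repeat-notation string, or label vector.
#' @param name Optional name.
#' @return A [cg_sequence()].
#' @export
as_cg_sequence <- function(x, name = NULL) {
  if (inherits(x, "cg_sequence")) return(x)
  if (is.character(x) && length(x) == 1 && nchar(x) > 1) {
    return(parse_sequence(x, name = name))
  }
  cg_sequence(x, name = name)
}

#' Composition fractions of a sequence
#'
#' @param seq A [cg_sequence()] (or anything [as_cg_sequence()] accepts).
#' @return A tibble with one row: `name`, `n`, `f_H` (fraction cohesive),
#'   `f_plus`, `f_minus`, `f_P`. The four fractions sum to one.
#' @export
composition <- function(seq) {
  seq <- as_cg_sequence(seq)
  n <- length(seq)
  tibble::tibble(
    name = seq_name(seq),
    n = n,
    f_H = sum(seq == "H") / n,
    f_plus = sum(seq == "+") / n,
    f_minus = sum(seq == "-") / n,
    f_P = sum(seq == "P") / n
  )
}

#' Generate an H/P patch sequence
#'
#' Builds a chain of cohesive (`H`) and neutral (`P`) monomers arranged as
#' 1:1-interleaved blocks ("patches") of the given size, the family used to
#' study how cohesive patchiness at fixed composition changes chain
#' dimensions. If a count is not divisible by the patch size, the remainder
#' is appended at the end as a final pair of shorter blocks (documented
#' remainder-placement rule).
#'
#' @param n_cohesive Number of `H` monomers.
#' @param n_neutral Number of `P` monomers.
#' @param patch_size Block size (1 gives strict alternation).
#' @return A [cg_sequence()].
#' @examples
#' generate_patch_sequence(30, 30, 1)  # same as "(HP)30"
#' @export
generate_patch_sequence <- function(n_cohesive, n_neutral, patch_size) {
  stopifnot(n_cohesive >= 0, n_neutral >= 0, patch_size >= 1)
  if (patch_size > max(n_cohesive, 1)) stop("patch_size larger than the number of cohesive monomers")
  labels <- character(0)
  h_left <- n_cohesive
  p_left <- n_neutral
  while (h_left > 0 || p_left > 0) {
    kh <- min(patch_size, h_left)
    kp <- min(patch_size, p_left)
    labels <- c(labels, rep("H", kh), rep("P", kp))
    h_left <- h_left - kh
    p_left <- p_left - kp
  }
  cg_sequence(labels, name = sprintf("patch_H%d_P%d_k%d", n_cohesive, n_neutral, patch_size))
}

#' Generate a polyampholyte sequence
#'
#' @param n_pos Number of positively charged monomers.
#' @param n_neg Number of negatively charged monomers.
#' @param mode `"alternating"`, `"blocks"` or `"shuffled"`.
#' @param block_size Block size for `mode = "blocks"`; must divide both
#'   counts. Blocks of negatives precede blocks of positives within each
#'   period, so `(25, 25, "blocks", 5)` is five repeats of 5 negative then
#'   5 positive monomers.
#' @param seed Integer seed for `mode = "shuffled"` (required there);
#'   the same seed reproduces the same sequence.
#' @return A [cg_sequence()].
#' @export
generate_polyampholyte <- function(n_pos, n_neg,
                                   mode = c("alternating", "blocks", "shuffled"),
                                   block_size = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_pos >= 0, n_neg >= 0, n_pos + n_neg >= 2)
  labels <- switch(mode,
    alternating = {
      k <- min(n_pos, n_neg)
      base <- as.vector(rbind(rep("+", k), rep("-", k)))
      c(base, rep("+", n_pos - k), rep("-", n_neg - k))
    },
    blocks = {
      if (is.null(block_size)) stop("block_size is required for mode = 'blocks'")
      if (n_pos %% block_size != 0 || n_neg %% block_size != 0) {
        stop("block_size must divide both n_pos and n_neg")
      }
      reps <- min(n_pos, n_neg) %/% block_size
      per <- c(rep("-", block_size), rep("+", block_size))
      c(rep(per, reps), rep("-", n_neg - reps * block_size),
        rep("+", n_pos - reps * block_size))
    },
    shuffled = {
      if (is.null(seed)) stop("seed is required for mode = 'shuffled'")
      pool <- c(rep("+", n_pos), rep("-", n_neg))
      withr_seed(seed, sample(pool))
    }
  )
  nm <- sprintf("ampholyte_%dp_%dn_%s%s", n_pos, n_neg, mode,
                if (mode == "blocks") block_size else "")
  cg_sequence(labels, name = nm)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default residue-to-alphabet reduction map
#'
#' Maps the 20 amino acids onto the four-letter model: K and R to `"+"`,
#' D and E to `"-"`, the strongly hydrophobic/aromatic residues
#' F, L, I, V, M, Y, W to cohesive `"H"`, and everything else to neutral
#' `"P"`.
#'
#' @return Named character vector mapping residue letters to model labels.
#' @export
default_reduction_map <- function() {
  m <- rep("P", 26)
  names(m) <- LETTERS
  m[c("K", "R")] <- "+"
  m[c("D", "E")] <- "-"
  m[c("F", "L", "I", "V", "M", "Y", "W")] <- "H"
  m
}

#' Read sequences from a FASTA file and reduce to the four-letter alphabet
#'
#' @param path FASTA file of amino-acid sequences.
#' @param map Named character vector mapping residue letters to
#'   `monomer_alphabet()` labels; defaults to [default_reduction_map()].
#' @return A list of [cg_sequence()] objects, named by FASTA header.
#' @export
read_fasta_sequences <- function(path, map = default_reduction_map()) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  lapply(seq_along(aa), function(i) {
    res <- strsplit(toupper(as.character(aa[[i]])), "")[[1]]
    unknown <- setdiff(unique(res), names(map))
    if (length(unknown) > 0) {
      stop("residue(s) not covered by the reduction map: ",
           paste(unknown, collapse = ", "))
    }
    cg_sequence(unname(map[res]), name = names(aa)[i])
  })
}
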