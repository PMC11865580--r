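# Site-saturation mutagenesis analysis: log-enrichment matrices from
# selected vs reference deep-sequencing pools and per-position Shannon
# entropy conservation profiles.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in fixed alphabetical order; all SSM count
#' matrices are position x 20 over this column order.
#' @return character vector of length 20.
#' @export
aa_alphabet <- function()
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.check_counts <- function(m, what, L) {
  m <- as.matrix(m)
  if (ncol(m) != 20)
    stop(what, " must have 20 columns (canonical amino acids), has ",
         ncol(m))
  if (!is.null(colnames(m))) {
    if (!setequal(colnames(m), aa_alphabet()))
      stop(what, " column names are not the 20 canonical amino acids")
    m <- m[, aa_alphabet(), drop = FALSE]
  } else colnames(m) <- aa_alphabet()
  if (nrow(m) != L)
    stop(what, " has ", nrow(m), " rows but the parent sequence has ",
         L, " positions")
  if (any(m < 0)) stop(what, " contains negative counts")
  if (any(m != round(m))) stop(what, " contains non-integer counts")
  rownames(m) <- seq_len(L)
  m
}

#' SSM count container
#'
#' Bundles a parent sequence with position x 20 count matrices for the
#' selected and reference pools (1-based positions; fixed alphabetical
#' amino-acid column order).
#'
#' @param parent_sequence parent amino-acid string.
#' @param selected,reference non-negative integer count matrices.
#' @return An `ssm_counts` object.
#' @export
ssm_counts <- function(parent_sequence, selected, reference) {
  parent_sequence <- toupper(parent_sequence)
  aa <- strsplit(parent_sequence, "")[[1]]
  if (!length(aa) || !all(aa %in% aa_alphabet()))
    stop("parent_sequence must be non-empty over the 20 canonical ",
         "amino acids")
  L <- length(aa)
  structure(list(parent_sequence = parent_sequence,
                 selected = .check_counts(selected, "selected", L),
                 reference = .check_counts(reference, "reference", L)),
            class = "ssm_counts")
}

#' @export
print.ssm_counts <- function(x, ...) {
  cat("ssm_counts:", nchar(x$parent_sequence), "positions;",
      sum(x$selected), "selected /", sum(x$reference),
      "reference reads\n")
  invisible(x)
}

#' Log2 enrichment matrix
#'
#' Per-cell enrichment `E[p, a] = log2(f_sel[p, a] / f_ref[p, a])` where
#' frequencies are pseudocount-adjusted and normalized over the whole
#' pool: `f = (count + pseudocount) / sum(count + pseudocount)`. A
#' positive pseudocount guarantees finite values everywhere. Positive
#' values mean the variant was enriched by selection.
#'
#' @param counts an `ssm_counts` object.
#' @param pseudocount added to every cell before normalization (default
#'   1).
#' @param mask_parent set parent-residue cells to `NA` (they carry
#'   wild-type synonym reads; retained by default).
#' @return position x 20 matrix of class `enrichment_matrix` with
#'   attributes `pseudocount` and `parent_sequence`.
#' @export
log_enrichment <- function(counts, pseudocount = 1, mask_parent = FALSE) {
  stopifnot(inherits(counts, "ssm_counts"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  fs <- counts$selected + pseudocount
  fr <- counts$reference + pseudocount
  if (sum(fr) <= 0) stop("reference pool has zero total counts")
  E <- log2((fs / sum(fs)) / (fr / sum(fr)))
  if (mask_parent) {
    aa <- strsplit(counts$parent_sequence, "")[[1]]
    E[cbind(seq_along(aa), match(aa, aa_alphabet()))] <- NA_real_
  }
  structure(E, pseudocount = pseudocount,
            parent_sequence = counts$parent_sequence,
            class = c("enrichment_matrix", "matrix"))
}

#' Per-position Shannon entropy
#'
#' Entropy in bits of the amino-acid frequency distribution at each
#' position, computed from the selected pool by default (low entropy =
#' conserved under selection). `0 * log 0` is taken as 0; the maximum is
#' `log2(20) ~ 4.3219` bits at a uniform distribution.
#'
#' @param counts an `ssm_counts` object.
#' @param pool `"selected"` (default, the conservation readout) or
#'   `"reference"`.
#' @param pseudocount added to every cell before normalization (default
#'   0).
#' @return numeric vector of class `entropy_profile` (bits, one per
#'   position).
#' @export
position_entropy <- function(counts, pool = c("selected", "reference"),
                             pseudocount = 0) {
  stopifnot(inherits(counts, "ssm_counts"))
  pool <- match.arg(pool)
  m <- counts[[pool]] + pseudocount
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("undefined entropy: zero total counts at position(s) ",
         paste(which(tot <= 0), collapse = ", "),
         " with pseudocount ", pseudocount)
  q <- m / tot
  H <- -rowSums(ifelse(q > 0, q * log2(q), 0))
  structure(as.numeric(H), pool = pool, class = "entropy_profile")
}

#' Conservation classes from an entropy profile
#'
#' Classifies positions by entropy quantile within the profile:
#' `conserved` strictly below the low quantile, `variable` strictly above
#' the high quantile, `intermediate` otherwise. A constant profile
#' collapses both quantiles onto the common value, so every position is
#' intermediate.
#'
#' @param profile an `entropy_profile` (or numeric vector of entropies).
#' @param quantiles low/high quantile pair (default 0.25, 0.75).
#' @return character vector of classes, one per position.
#' @export
conservation_classes <- function(profile, quantiles = c(0.25, 0.75)) {
  h <- as.numeric(profile)
  if (!length(h)) stop("empty entropy profile")
  qs <- quantile(h, quantiles, names = FALSE)
  ifelse(h < qs[1], "conserved",
         ifelse(h > qs[2], "variable", "intermediate"))
}

#' Simulate an SSM sorting experiment
#'
#' Synthetic-data generator emulating a FACS sort of a site-saturation
#' library read out by deep sequencing. The reference pool draws each
#' position's reads from a uniform multinomial over the 20 amino acids
#' (every variant present, wild-type synonyms included); the selected pool
#' reweights the reference frequencies by a per-variant fitness: parent
#' residues have fitness 1, substitutions at conserved positions fitness
#' `conserved_fitness`, and substitutions elsewhere log-normal fitness
#' around 1 (so variable positions stay variable after selection).
#'
#' @param parent_sequence parent amino-acid string.
#' @param conserved_positions 1-based positions generated as conserved
#'   (e.g. interface and core).
#' @param depth reads per position per pool (default 10000).
#' @param conserved_fitness fitness of substitutions at conserved
#'   positions (default 0.005, i.e. strongly deleterious: interface and
#'   core substitutions deplete to near zero under sorting).
#' @param fitness_sdlog log-normal spread of substitution fitness at
#'   variable positions (default 0.5).
#' @param seed RNG seed.
#' @return list: `counts` (an `ssm_counts`), `fitness` (position x 20
#'   matrix, the ground truth), `conserved_positions`.
#' @export
simulate_ssm_counts <- function(parent_sequence, conserved_positions,
                                depth = 10000, conserved_fitness = 0.005,
                                fitness_sdlog = 0.5, seed = 0L) {
  parent_sequence <- toupper(parent_sequence)
  aa <- strsplit(parent_sequence, "")[[1]]
  L <- length(aa)
  stopifnot(all(conserved_positions >= 1 & conserved_positions <= L))
  with_seed(seed, {
    fitness <- matrix(exp(rnorm(L * 20, 0, fitness_sdlog)), L, 20,
                      dimnames = list(seq_len(L), aa_alphabet()))
    fitness[conserved_positions, ] <- conserved_fitness
    fitness[cbind(seq_len(L), match(aa, aa_alphabet()))] <- 1
    ref <- sel <- matrix(0L, L, 20)
    for (p in seq_len(L)) {
      ref[p, ] <- rmultinom(1, depth, rep(1 / 20, 20))
      w <- fitness[p, ] / 20
      sel[p, ] <- rmultinom(1, depth, w / sum(w))
    }
    list(counts = ssm_counts(parent_sequence, sel, ref),
         fitness = fitness,
         conserved_positions = sort(unique(conserved_positions)))
  })
}

#' Read SSM counts from TSV
#'
#' Accepts two dialects. Long form: a single TSV with columns `position`,
#' `aa`, `pool` (`selected`/`reference`) and `count`. Matrix form: two
#' TSVs (selected and reference), each with a `position` column followed
#' by 20 amino-acid columns. Positions are 1-based relative to the parent
#' sequence.
#'
#' @param parent_sequence parent amino-acid string.
#' @param path long-form TSV path (ignored when `selected`/`reference`
#'   given).
#' @param selected,reference matrix-form TSV paths.
#' @return An `ssm_counts` object.
#' @export
read_ssm_counts <- function(parent_sequence, path = NULL, selected = NULL,
                            reference = NULL) {
  L <- nchar(parent_sequence)
  empty <- function() matrix(0L, L, 20,
                             dimnames = list(NULL, aa_alphabet()))
  if (!is.null(path)) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("position", "aa", "pool", "count")
    if (!all(need %in% names(df)))
      stop("long-form SSM TSV needs columns: ",
           paste(need, collapse = ", "))
    mats <- list(selected = empty(), reference = empty())
    for (i in seq_len(nrow(df))) {
      pool <- df$pool[i]
      if (!pool %in% names(mats)) stop("unknown pool: ", pool)
      mats[[pool]][df$position[i], df$aa[i]] <-
        mats[[pool]][df$position[i], df$aa[i]] + df$count[i]
    }
    return(ssm_counts(parent_sequence, mats$selected, mats$reference))
  }
  read_mat <- function(p) {
    df <- read.table(p, header = TRUE, sep = "\t", check.names = FALSE)
    if (!"position" %in% names(df))
      stop("matrix-form SSM TSV needs a 'position' column: ", p)
    m <- empty()
    m[df$position, ] <- as.matrix(df[, aa_alphabet()])
    m
  }
  ssm_counts(parent_sequence, read_mat(selected), read_mat(reference))
}

#' Write an enrichment matrix or entropy profile as TSV
#' @param x an `enrichment_matrix` or `entropy_profile`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ssm_tsv <- function(x, path) {
  if (inherits(x, "enrichment_matrix")) {
    df <- data.frame(position = seq_len(nrow(x)),
                     as.data.frame(unclass(x)), check.names = FALSE)
  } else {
    df <- data.frame(position = seq_along(x),
                     entropy_bits = as.numeric(x))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a per-residue profile onto structure B-factors
#'
#' Writes a PDB whose B-factor column carries a per-residue value (for
#' example a Shannon-entropy conservation profile), for structure-viewer
#' coloring.
#'
#' @param model a `structure_model`.
#' @param values named numeric vector, names = residue numbers, or a
#'   plain vector aligned to the sorted residue numbers of `chain`.
#' @param path output PDB path.
#' @param chain chain to annotate (others get 0).
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(model, values, path, chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (is.null(chain)) chain <- model_chains(model)[1]
  resnos <- sort(unique(at$resno[at$chain == chain]))
  if (is.null(names(values))) {
    if (length(values) != length(resnos))
      stop("need one value per residue (", length(resnos), "), got ",
           length(values))
    names(values) <- resnos
  }
  b <- rep(0, nrow(at))
  idx <- at$chain == chain & as.character(at$resno) %in% names(values)
  b[idx] <- values[as.character(at$resno[idx])]
  write_structure(model, path, b = b)
}
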