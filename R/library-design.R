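# Degenerate-codon combinatorial library design and design-metric
# filtering. Codon expansion uses the standard genetic code and IUPAC
# nucleotide ambiguity codes from Biostrings; the covering-codon search is
# exhaustive over all 15^3 = 3375 degenerate triplets.

.iupac <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  m[nchar(names(m)) == 1 & names(m) %in%
      c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
        "V", "H", "D", "B", "N")]
}

#' Expand a degenerate codon
#'
#' Enumerates the Cartesian product of the IUPAC base sets of a 3-symbol
#' degenerate codon and translates each concrete codon with the standard
#' genetic code. Stops are coded as `"*"`.
#'
#' @param triplet 3 IUPAC nucleotide symbols (e.g. `"NNK"`, `"RAC"`).
#' @return A `degenerate_codon`: list with `triplet`, `dna_degeneracy`
#'   (product of base-set sizes) and `encoded_aas` (named integer
#'   multiset over amino acids and `"*"`).
#' @export
expand_degenerate_codon <- function(triplet) {
  triplet <- toupper(triplet)
  sym <- strsplit(triplet, "")[[1]]
  if (length(sym) != 3)
    stop("degenerate codon must have exactly 3 symbols: ", triplet)
  iupac <- .iupac()
  bad <- setdiff(sym, names(iupac))
  if (length(bad))
    stop("invalid IUPAC nucleotide symbol(s): ",
         paste(bad, collapse = ", "))
  sets <- strsplit(iupac[sym], "")
  codons <- apply(expand.grid(sets[[1]], sets[[2]], sets[[3]],
                              stringsAsFactors = FALSE),
                  1, paste, collapse = "")
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  tab <- table(aas)
  structure(list(triplet = triplet,
                 dna_degeneracy = length(codons),
                 encoded_aas = setNames(as.integer(tab), names(tab))),
            class = "degenerate_codon")
}

#' @export
print.degenerate_codon <- function(x, ...) {
  cat("degenerate codon ", x$triplet, ": ", x$dna_degeneracy,
      " codons -> {",
      paste(sprintf("%s:%d", names(x$encoded_aas), x$encoded_aas),
            collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Lazily built table of all 3375 degenerate triplets with their encodings.
.all_degenerate_codons <- function() {
  if (!is.null(.cb_env$codon_table)) return(.cb_env$codon_table)
  syms <- names(.iupac())
  grid <- expand.grid(b3 = syms, b2 = syms, b1 = syms,
                      stringsAsFactors = FALSE)
  triplets <- paste0(grid$b1, grid$b2, grid$b3)
  tab <- lapply(triplets, expand_degenerate_codon)
  .cb_env$codon_table <- tab
  tab
}

#' Design a degenerate codon covering a desired amino-acid set
#'
#' Brute-force search over all 3375 degenerate triplets. Codons whose
#' encoded set covers `desired` (and, with `forbid_stop`, encodes no
#' stop) are ranked by fewest off-target distinct residues (stops count
#' as off-target), then smallest DNA degeneracy, then lexicographic
#' triplet.
#'
#' @param desired non-empty subset of the 20 canonical amino acids
#'   (character vector or single string).
#' @param forbid_stop exclude stop-encoding codons (default TRUE).
#' @return data.frame of covering codons in rank order: `triplet`,
#'   `dna_degeneracy`, `n_encoded`, `n_off_target`, `encodes_stop`,
#'   `encoded`.
#' @export
design_degenerate_codon <- function(desired, forbid_stop = TRUE) {
  if (length(desired) == 1 && nchar(desired[1]) > 1)
    desired <- strsplit(desired, "")[[1]]
  desired <- unique(toupper(desired))
  if (!length(desired) || !all(desired %in% aa_alphabet()))
    stop("desired must be a non-empty subset of the 20 canonical ",
         "amino acids")
  score <- function(allow_stop) {
    rows <- lapply(.all_degenerate_codons(), function(dc) {
      enc <- names(dc$encoded_aas)
      if (!all(desired %in% enc)) return(NULL)
      has_stop <- "*" %in% enc
      if (!allow_stop && has_stop) return(NULL)
      data.frame(triplet = dc$triplet,
                 dna_degeneracy = dc$dna_degeneracy,
                 n_encoded = length(enc),
                 n_off_target = length(setdiff(enc, desired)),
                 encodes_stop = has_stop,
                 encoded = paste(sort(enc), collapse = ""),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(out)
    out <- out[order(out$n_off_target, out$dna_degeneracy, out$triplet), ]
    rownames(out) <- NULL
    out
  }
  out <- score(allow_stop = !forbid_stop)
  if (is.null(out)) {
    alt <- score(allow_stop = TRUE)
    stop("no stop-free degenerate codon covers {",
         paste(sort(desired), collapse = ""), "}; best stop-permitting ",
         "alternative: ", alt$triplet[1], " (", alt$encoded[1], ")")
  }
  out
}

#' Build a combinatorial degenerate-codon library
#'
#' Chooses the top-ranked covering codon for each varied position and
#' accounts the library's combinatorial diversity against a
#' transformation-capacity budget (yeast transformation efficiencies are
#' around 1e7 DNA molecules, so the capacity check compares DNA
#' diversity; protein diversity is reported alongside).
#'
#' @param parent_sequence parent amino-acid string.
#' @param desired data.frame with columns `position` and `aas` (string of
#'   desired residues per position), or a named list position -> residue
#'   vector.
#' @param capacity transformation capacity (default 1e7).
#' @param forbid_stop exclude stop-encoding codons (default TRUE).
#' @param require_parent require each desired set to retain the parent
#'   residue (default TRUE; relax for parent-excluding libraries).
#' @return A `library_spec`: per-position codon table, `dna_diversity`,
#'   `protein_diversity`, `capacity`, `fits_capacity`.
#' @export
build_library <- function(parent_sequence, desired, capacity = 1e7,
                          forbid_stop = TRUE, require_parent = TRUE) {
  parent_sequence <- toupper(parent_sequence)
  aa <- strsplit(parent_sequence, "")[[1]]
  if (is.data.frame(desired)) {
    stopifnot(all(c("position", "aas") %in% names(desired)))
    pos <- desired$position
    sets <- strsplit(toupper(desired$aas), "")
  } else {
    pos <- as.integer(names(desired))
    sets <- lapply(desired, function(s)
      if (length(s) == 1 && nchar(s) > 1) strsplit(toupper(s), "")[[1]]
      else toupper(s))
  }
  if (any(pos < 1 | pos > length(aa)))
    stop("desired positions outside the parent sequence (1..",
         length(aa), ")")
  rows <- list(); errs <- character()
  for (i in seq_along(pos)) {
    p <- pos[i]; set <- unique(sets[[i]])
    if (require_parent && !(aa[p] %in% set))
      stop("desired set at position ", p, " omits the parent residue ",
           aa[p], " (set require_parent = FALSE to allow)")
    ranked <- tryCatch(design_degenerate_codon(set,
                                               forbid_stop = forbid_stop),
                       error = function(e) conditionMessage(e))
    if (is.character(ranked)) {
      errs <- c(errs, paste0("position ", p, ": ", ranked))
      next
    }
    top <- ranked[1, ]
    rows[[length(rows) + 1]] <- data.frame(
      position = p, parent_aa = aa[p],
      desired = paste(sort(set), collapse = ""),
      triplet = top$triplet, dna_degeneracy = top$dna_degeneracy,
      n_encoded = top$n_encoded, n_off_target = top$n_off_target,
      stringsAsFactors = FALSE)
  }
  if (length(errs))
    stop("no covering codon for ", length(errs), " position(s):\n  ",
         paste(errs, collapse = "\n  "))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), parent_aa = character(),
               desired = character(), triplet = character(),
               dna_degeneracy = integer(), n_encoded = integer(),
               n_off_target = integer())
  dna_div <- prod(as.numeric(tab$dna_degeneracy))
  prot_div <- prod(as.numeric(tab$n_encoded))
  structure(list(positions = tab, dna_diversity = dna_div,
                 protein_diversity = prot_div, capacity = capacity,
                 fits_capacity = dna_div <= capacity),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat("library_spec:", nrow(x$positions), "varied positions\n")
  cat("  DNA diversity:", format(x$dna_diversity, big.mark = ","),
      "| protein diversity:",
      format(x$protein_diversity, big.mark = ","), "\n")
  cat("  capacity:", format(x$capacity, big.mark = ","), "->",
      if (x$fits_capacity) "fits" else "EXCEEDS capacity", "\n")
  invisible(x)
}

#' Design-metric filter specification
#'
#' The interface-design admission thresholds: predicted binding energy
#' ddG below -40 (Rosetta units), contact molecular surface above 400
#' (Angstrom^2), AlphaFold2 predicted aligned error below 10; optionally
#' mean pLDDT of at least 80. Boundary rows (exactly at a bound) pass but
#' are flagged.
#'
#' @param ddg,contact_molecular_surface,pae,plddt bounds; set a bound to
#'   `NULL` to drop its rule.
#' @return data.frame of rules (metric, direction, bound) of class
#'   `filter_spec`, in application order.
#' @export
design_filter_spec <- function(ddg = -40, contact_molecular_surface = 400,
                               pae = 10, plddt = NULL) {
  rules <- list()
  add <- function(metric, direction, bound) {
    if (!is.null(bound))
      rules[[length(rules) + 1]] <<- data.frame(
        metric = metric, direction = direction, bound = bound,
        stringsAsFactors = FALSE)
  }
  add("ddg", "le", ddg)
  add("contact_molecular_surface", "ge", contact_molecular_surface)
  add("pae", "le", pae)
  add("plddt", "ge", plddt)
  out <- do.call(rbind, rules)
  class(out) <- c("filter_spec", "data.frame")
  out
}

#' Apply design-metric filters to a metrics table
#'
#' A row survives iff it passes every rule; attrition is reported per
#' rule in application order, among rows surviving the previous rules.
#' Missing values fail the rule and are counted separately. The survivor
#' set is order-invariant; only the attrition breakdown depends on rule
#' order.
#'
#' @param metrics data.frame with one named numeric column per rule
#'   metric.
#' @param spec a `filter_spec` (default: [design_filter_spec()]).
#' @return list of class `design_filter_result`: `survivors` (surviving
#'   rows, with an `at_boundary` flag), `attrition` (per-rule counts).
#' @export
apply_design_filters <- function(metrics, spec = design_filter_spec()) {
  stopifnot(is.data.frame(metrics))
  miss_col <- setdiff(spec$metric, names(metrics))
  if (length(miss_col))
    stop("metrics table lacks column(s): ",
         paste(miss_col, collapse = ", "))
  alive <- rep(TRUE, nrow(metrics))
  att <- list()
  boundary <- rep(FALSE, nrow(metrics))
  for (i in seq_len(nrow(spec))) {
    m <- spec$metric[i]; b <- spec$bound[i]
    v <- metrics[[m]]
    pass <- if (spec$direction[i] == "le") v <= b else v >= b
    is_na <- is.na(v)
    pass[is_na] <- FALSE
    n_fail <- sum(alive & !pass & !is_na)
    n_miss <- sum(alive & is_na)
    boundary <- boundary | (!is.na(v) & v == b)
    alive <- alive & pass
    att[[i]] <- data.frame(metric = m, direction = spec$direction[i],
                           bound = b, n_failed = n_fail,
                           n_missing = n_miss,
                           n_remaining = sum(alive),
                           stringsAsFactors = FALSE)
  }
  survivors <- metrics[alive, , drop = FALSE]
  survivors$at_boundary <- boundary[alive]
  structure(list(survivors = survivors,
                 attrition = do.call(rbind, att)),
            class = "design_filter_result")
}

#' @export
print.design_filter_result <- function(x, ...) {
  cat("design filter:", nrow(x$survivors), "survivor(s)\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}

#' Write a library spec as TSV
#' @param spec a `library_spec`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(spec, path) {
  stopifnot(inherits(spec, "library_spec"))
  write.table(spec$positions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
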