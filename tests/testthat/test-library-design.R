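# Independent expansion oracle: IUPAC sets and the standard genetic code
# spelled out locally, separate from the implementation's tables.
oracle_expand <- function(triplet) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", M = c("A", "C"),
                R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
                Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
                H = c("A", "C", "T"), D = c("A", "G", "T"),
                B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  sym <- strsplit(triplet, "")[[1]]
  codons <- apply(expand.grid(iupac[[sym[1]]], iupac[[sym[2]]],
                              iupac[[sym[3]]]), 1, paste, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  table(unname(gc[codons]))
}

test_that("degenerate codons expand against the genetic code", {
  k <- expand_degenerate_codon("AAA")
  expect_equal(k$dna_degeneracy, 1)
  expect_equal(k$encoded_aas, c(K = 1L))

  rac <- expand_degenerate_codon("RAC")
  expect_equal(rac$dna_degeneracy, 2)
  expect_equal(sort(names(rac$encoded_aas)), c("D", "N"))

  nnk <- expand_degenerate_codon("NNK")
  expect_equal(nnk$dna_degeneracy, 32)
  expect_equal(length(setdiff(names(nnk$encoded_aas), "*")), 20)
  expect_equal(nnk$encoded_aas[["*"]], 1L)

  expect_error(expand_degenerate_codon("AXZ"), "invalid IUPAC")
  expect_error(expand_degenerate_codon("AAAA"), "3 symbols")
})

test_that("codon design finds minimal covering codons", {
  top <- design_degenerate_codon(c("N", "D"))
  expect_equal(top$triplet[1], "RAC")
  expect_equal(top$n_off_target[1], 0)

  expect_equal(design_degenerate_codon("W")$triplet[1], "TGG")
  expect_equal(design_degenerate_codon("W")$dna_degeneracy[1], 1)

  all20 <- design_degenerate_codon(aa_alphabet(), forbid_stop = FALSE)
  expect_equal(all20$dna_degeneracy[1], 32)  # NNK/NNS beat NNN
  expect_equal(all20$triplet[1], "NNK")
})

test_that("stop-free coverage failures report the best alternative", {
  expect_error(design_degenerate_codon(c("A", "C", "D", "E")),
               "best stop-permitting alternative")
})

test_that("every returned codon covers the desired set (expand/design duality)", {
  set.seed(9)
  for (i in 1:15) {
    desired <- sample(aa_alphabet(), sample(1:8, 1))
    ranked <- tryCatch(design_degenerate_codon(desired),
                       error = function(e) NULL)
    if (is.null(ranked)) next
    for (j in seq_len(min(5, nrow(ranked)))) {
      enc <- names(expand_degenerate_codon(ranked$triplet[j])$encoded_aas)
      expect_true(all(desired %in% enc))
      expect_false("*" %in% enc)
    }
  }
})

test_that("the top-ranked codon matches an independent exhaustive search", {
  syms <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
            "V", "H", "D", "B", "N")
  grid <- expand.grid(b3 = syms, b2 = syms, b1 = syms,
                      stringsAsFactors = FALSE)
  triplets <- paste0(grid$b1, grid$b2, grid$b3)
  oracle_tabs <- lapply(triplets, oracle_expand)
  oracle_best <- function(desired) {
    best <- NULL
    for (i in seq_along(triplets)) {
      tp <- triplets[i]
      tab <- oracle_tabs[[i]]
      enc <- names(tab)
      if (!all(desired %in% enc) || "*" %in% enc) next
      cand <- list(tp = tp, off = length(setdiff(enc, desired)),
                   deg = sum(tab))
      if (is.null(best) || cand$off < best$off ||
          (cand$off == best$off && cand$deg < best$deg) ||
          (cand$off == best$off && cand$deg == best$deg && tp < best$tp))
        best <- cand
    }
    best$tp
  }
  set.seed(17)
  cases <- replicate(8, sample(aa_alphabet(), sample(1:6, 1)),
                     simplify = FALSE)
  for (desired in cases) {
    got <- tryCatch(design_degenerate_codon(desired)$triplet[1],
                    error = function(e) NA_character_)
    want <- oracle_best(desired)
    if (is.null(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("library diversity is an exact product checked against capacity", {
  # three positions with exactly coverable sets of sizes 2, 4, 4
  parent <- "NTT"
  desired <- data.frame(position = 1:3,
                        aas = c("ND", "TPAS", "TSAG"))
  lib <- build_library(parent, desired)
  expect_equal(lib$protein_diversity, 2 * 4 * 4)
  expect_equal(lib$dna_diversity, 2 * 4 * 4)
  expect_true(lib$fits_capacity)
  expect_true(all(lib$positions$n_off_target == 0))

  # 12 positions of exact 4-codon sets overflow a 1e7 transformation
  lib12 <- build_library(strrep("T", 12),
                         data.frame(position = 1:12, aas = "TPAS"))
  expect_equal(lib12$dna_diversity, 4^12)
  expect_equal(lib12$dna_diversity, 16777216)
  expect_false(lib12$fits_capacity)
  expect_lte(lib12$protein_diversity, lib12$dna_diversity)

  # empty request: diversity 1, fits trivially
  lib0 <- build_library("ACDE", list())
  expect_equal(lib0$dna_diversity, 1)
  expect_true(lib0$fits_capacity)
})

test_that("the parent residue must stay encodable unless relaxed", {
  expect_error(build_library("W", data.frame(position = 1, aas = "ND")),
               "parent residue")
  lib <- build_library("W", data.frame(position = 1, aas = "ND"),
                       require_parent = FALSE)
  expect_equal(lib$positions$triplet, "RAC")
})

test_that("design filters apply the admission thresholds in order", {
  m <- data.frame(ddg = c(-50, -30, -50),
                  contact_molecular_surface = c(500, 500, 300),
                  pae = c(5, 5, 5))
  res <- apply_design_filters(m)
  expect_equal(nrow(res$survivors), 1)
  expect_equal(res$survivors$ddg, -50)
  expect_equal(res$attrition$n_failed, c(1, 1, 0))

  empty <- apply_design_filters(m[0, ])
  expect_equal(nrow(empty$survivors), 0)
  expect_true(all(empty$attrition$n_failed == 0))

  expect_error(apply_design_filters(data.frame(ddg = 1)), "lacks column")
})

test_that("filter survivors match a brute-force recount and ignore rule order", {
  set.seed(23)
  m <- data.frame(ddg = runif(100, -80, 0),
                  contact_molecular_surface = runif(100, 200, 600),
                  pae = runif(100, 2, 18))
  res <- apply_design_filters(m)
  brute <- m$ddg <= -40 & m$contact_molecular_surface >= 400 & m$pae <= 10
  expect_equal(nrow(res$survivors), sum(brute))
  expect_equal(res$survivors$ddg, m$ddg[brute])

  spec_rev <- design_filter_spec()[3:1, ]
  class(spec_rev) <- c("filter_spec", "data.frame")
  res_rev <- apply_design_filters(m, spec_rev)
  expect_equal(sort(res_rev$survivors$ddg), sort(res$survivors$ddg))
})

test_that("missing metric values fail their rule and are counted apart", {
  m <- data.frame(ddg = c(-50, NA, -50),
                  contact_molecular_surface = c(500, 500, NA),
                  pae = c(5, 5, 5))
  res <- apply_design_filters(m)
  expect_equal(nrow(res$survivors), 1)
  expect_equal(res$attrition$n_missing, c(1, 1, 0))
})

test_that("boundary rows survive but are flagged", {
  m <- data.frame(ddg = c(-40, -50), contact_molecular_surface = c(400, 500),
                  pae = c(10, 5))
  res <- apply_design_filters(m)
  expect_equal(nrow(res$survivors), 2)
  expect_true(res$survivors$at_boundary[1])
  expect_false(res$survivors$at_boundary[2])
})
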