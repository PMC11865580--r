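#!/usr/bin/env Rscript
# Fetch the deposited crystal structures used by the external validation
# tests into tests/testthat/external-data/. Requires network access; the
# package and its test suite do not (the external checks simply report the
# data as unavailable).
#
# The sequence checks additionally need the published supplementary
# sequences of the optimized binders and their parents, saved manually as
# tests/testthat/external-data/binder_pairs.fasta with records named
#   5HCS_TGFBR2_0, 5HCS_TGFBR2_1, 5HCS_CTLA4_0, 5HCS_CTLA4_1,
#   5HCS_PDL1_0, 5HCS_PDL1_1

dest <- file.path("tests", "testthat", "external-data")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)
for (id in c("8G4K", "8GAB", "8GAC", "8GAD")) {
  out <- file.path(dest, paste0(id, ".pdb"))
  if (file.exists(out)) next
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
  message("fetching ", url)
  tryCatch(download.file(url, out, quiet = TRUE, mode = "wb"),
           error = function(e) message("  failed: ", conditionMessage(e)))
}
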