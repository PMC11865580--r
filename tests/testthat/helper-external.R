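# Locator for external validation data (deposited PDB entries and the
# published supplementary sequences). These are third-party artifacts that
# cannot be redistributed inside the package; scripts/fetch_external.R
# downloads the structures into tests/testthat/external-data/ when network
# access is available.
external_data_file <- function(name) {
  candidates <- c(test_path("external-data", name),
                  system.file("extdata", "external", name,
                              package = "concavebind"))
  hit <- candidates[file.exists(candidates) & nzchar(candidates)]
  if (length(hit)) hit[1] else candidates[1]
}
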