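#!/usr/bin/env Rscript
# Downloads the four transthyretin coordinate sets used by the
# real-structure checks (native 1DVQ, amyloid-resistant 1GKO, aggressive
# 1G1O, amyloid fibril 6SDZ) into tests/testthat/fixtures-real/.
# Requires network access; no test generates these files itself and the
# rest of the suite runs without them.

ids <- c("1DVQ", "1GKO", "1G1O", "6SDZ")
dest_dir <- file.path("tests", "testthat", "fixtures-real")
dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)

for (id in ids) {
  dest <- file.path(dest_dir, paste0(id, ".pdb"))
  if (file.exists(dest)) {
    message(id, " already present")
    next
  }
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
  message("fetching ", url)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
}
message("done; files in ", dest_dir)
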