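# Regenerates the packaged fixtures under inst/extdata/.
# Run from the package root with the package loadable via pkgload.
pkgload::load_all(".", quiet = TRUE)

fix <- make_synthetic_rcrs() # default documented seed

# FASTA, 70-column wrapped
seq <- fix$reference$sequence
lines <- substring(seq, seq(1, nchar(seq), 70),
                   pmin(seq(1, nchar(seq), 70) + 69, nchar(seq)))
writeLines(c(">synthetic_rCRS synthetic stand-in (NC_012920 coordinates, generated sequence)",
             lines),
           "inst/extdata/synthetic_rcrs.fa")

readr::write_tsv(mt_gene_table(), "inst/extdata/mt_annotation.tsv")

# MITOMAP-style lookup snapshot: published population frequencies for the
# variants used in the cross-sample examples.
known <- tibble::tribble(
  ~name,         ~gb_frequency_pct, ~associations,
  "m.8251G>A",   6.36,  "optic neuropathy; type 2 diabetes; Parkinson disease",
  "m.8567T>C",   0.18,  "Parkinson disease; breast cancer",
  "m.12684G>A",  0.10,  "",
  "m.12705C>T",  39.50, "hereditary optic neuropathy; dystonia; MERRF",
  "m.13062A>G",  0.04,  "",
  "m.13095T>C",  0.09,  "familial sensorineural hearing impairment",
  "m.13105A>G",  6.85,  "antibiotic-induced and non-syndromic deafness",
  "m.310T>C",    32.69, "Parkinson disease; hereditary optic neuropathy"
)
readr::write_tsv(known, "inst/extdata/known_variants_snapshot.tsv")

message("fixtures written")
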