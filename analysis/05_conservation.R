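#!/usr/bin/env Rscript

# Ortholog conservation of a binding-site cluster region, on a synthetic
# ortholog set derived from the cosmos: the human (hsa) entry is the
# family-cluster window of SYNG01 with its flanks; other primates carry
# wobble-preserving transitions inside the cluster (C->U, G->A) while the
# flanks stay untouched, and one species carries a 3-nt insert.

suppressPackageStartupMessages({
  library(mirsite)
  library(dplyr)
})

sc <- scenario_gastric_like(7L)
tx <- sc$transcripts[sc$transcripts$gene == "SYNG01", ]
fam <- sc$truth |> filter(gene == "SYNG01", mirna_id == "syn-fam-a")
flank <- 11L
region_start <- fam$start
region_end <- fam$start + fam$length - 1L
hsa <- substr(tx$seq, region_start - flank, region_end + flank)

mutate_at_pos <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}
core <- strsplit(substr(hsa, flank + 1L, flank + fam$length), "")[[1]]
c_pos <- flank + which(core == "C")  # alignment columns carrying C / G
g_pos <- flank + which(core == "G")

# wobble-preserving transitions inside the cluster region only:
# C->U keeps a G-U pair where the miRNA offers G; G->A keeps A-C
ptr <- mutate_at_pos(hsa, c_pos[1], "U")
ggo <- mutate_at_pos(hsa, g_pos[1], "A")
mml <- mutate_at_pos(mutate_at_pos(hsa, c_pos[1], "U"), c_pos[2], "U")

entries <- c(hsa = hsa, ptr = ptr, ggo = ggo, mml = mml)
set <- ortholog_set("SYNG01", entries, flank5_len = flank,
                    flank3_len = flank)
fi <- flank_identity(set)
cat(sprintf("Flank identity: 5' %.1f%% (%s), 3' %.1f%% (%s)\n",
            fi$pct5, ifelse(fi$all_identical5, "identical", "divergent"),
            fi$pct3, ifelse(fi$all_identical3, "identical", "divergent")))

# classify the hsa->species substitutions against the site's miRNA duplex
mir <- sc$mirnas$seq[sc$mirnas$id == "syn-fam-a"]
region_of <- function(s) substr(s, flank + 1L, flank + fam$length)
subs <- bind_rows(lapply(c("ptr", "ggo", "mml"), function(sp) {
  substitutions(region_of(hsa), region_of(entries[[sp]]),
                mirna_seq = mir) |>
    mutate(species = sp, .before = 1)
}))
readr::write_tsv(subs, "results/conservation_substitutions.tsv")
cat("\nSubstitutions vs hsa inside the cluster region:\n")
print(as.data.frame(subs), row.names = FALSE)
cat("\nAll", nrow(subs), "substitutions are",
    paste(unique(subs$klass), collapse = "/"),
    "- wobble-preserving ones cost at most",
    max(subs$ddG[subs$wobble_preserving], 0), "kJ/mole each.\n")

# an insert in one species, reported from the gapped alignment
with_insert <- paste0(substr(hsa, 1, flank + 6), "CGC",
                      substr(hsa, flank + 7, nchar(hsa)))
gapped <- vapply(entries, function(e) {
  paste0(substr(e, 1, flank + 6), "---",
         substr(e, flank + 7, nchar(e)))
}, character(1))
aln <- c(hsa2 = with_insert, gapped[c("ptr", "ggo", "mml")])
ins_set <- ortholog_set("SYNG01+ins", aln, flank, flank)
ins <- insert_report(ins_set)
cat("\nInsert detection on the gapped alignment:\n")
print(as.data.frame(ins), row.names = FALSE)
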