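# Small synthetic configurations and hand-built hit tables shared
# across the test files.

small_config <- function(seed = 1, vtoa = 3, atov = 2, und = 2, ...) {
  synth_config(
    seed = seed,
    n_host_genes = 20, n_virus_genes = 15, n_background = 30,
    n_planted_vtoa = vtoa, n_planted_atov = atov,
    n_planted_undetermined = und,
    ...
  )
}

# One annotated hit row with sensible filler for the alignment columns.
hit_row <- function(query, subject, bitscore, evalue = 1e-20,
                    source = "db", taxonomy = "unclassified") {
  tibble::tibble(
    query_id = query, subject_id = subject, percent_identity = 50,
    alignment_length = 100L, mismatches = 50L, gap_openings = 0L,
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = evalue, bitscore = bitscore,
    subject_source = source, subject_taxonomy = taxonomy
  )
}

hit_tbl <- function(...) dplyr::bind_rows(...)

# Raw 12-column rows (no annotation) for file IO tests.
raw_hit_line <- function(query, subject, evalue, bitscore) {
  paste(query, subject, "50.0", 100, 50, 0, 1, 100, 1, 100,
        format(evalue, scientific = TRUE), bitscore, sep = "\t")
}
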