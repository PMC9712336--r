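# R wrappers for the compiled routines (see src/init.cpp).

.nw_align_cpp <- function(a, b, match, mismatch, gap, band = -1L,
                          free_a_start = FALSE, free_a_end = FALSE,
                          free_b_start = FALSE, free_b_end = FALSE) {
    .Call(`_mucintr_nw_align_cpp`, a, b, match, mismatch, gap, band,
          free_a_start, free_a_end, free_b_start, free_b_end)
}

.push_gaps_right_cpp <- function(a, b) {
    .Call(`_mucintr_push_gaps_right_cpp`, a, b)
}

.shared_kmer_matrix_cpp <- function(seqs, k) {
    .Call(`_mucintr_shared_kmer_matrix_cpp`, seqs, k)
}
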