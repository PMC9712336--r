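// .Call glue and symbol registration for the compiled routines.
#include <Rcpp.h>
using namespace Rcpp;

List nw_align_cpp(std::string a, std::string b, double match, double mismatch, double gap, int band, bool free_a_start, bool free_a_end, bool free_b_start, bool free_b_end);
RcppExport SEXP _mucintr_nw_align_cpp(SEXP aSEXP, SEXP bSEXP, SEXP matchSEXP, SEXP mismatchSEXP, SEXP gapSEXP, SEXP bandSEXP, SEXP free_a_startSEXP, SEXP free_a_endSEXP, SEXP free_b_startSEXP, SEXP free_b_endSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< std::string >::type a(aSEXP);
    Rcpp::traits::input_parameter< std::string >::type b(bSEXP);
    Rcpp::traits::input_parameter< double >::type match(matchSEXP);
    Rcpp::traits::input_parameter< double >::type mismatch(mismatchSEXP);
    Rcpp::traits::input_parameter< double >::type gap(gapSEXP);
    Rcpp::traits::input_parameter< int >::type band(bandSEXP);
    Rcpp::traits::input_parameter< bool >::type free_a_start(free_a_startSEXP);
    Rcpp::traits::input_parameter< bool >::type free_a_end(free_a_endSEXP);
    Rcpp::traits::input_parameter< bool >::type free_b_start(free_b_startSEXP);
    Rcpp::traits::input_parameter< bool >::type free_b_end(free_b_endSEXP);
    rcpp_result_gen = Rcpp::wrap(nw_align_cpp(a, b, match, mismatch, gap, band, free_a_start, free_a_end, free_b_start, free_b_end));
    return rcpp_result_gen;
END_RCPP
}

List push_gaps_right_cpp(std::string a, std::string b);
RcppExport SEXP _mucintr_push_gaps_right_cpp(SEXP aSEXP, SEXP bSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< std::string >::type a(aSEXP);
    Rcpp::traits::input_parameter< std::string >::type b(bSEXP);
    rcpp_result_gen = Rcpp::wrap(push_gaps_right_cpp(a, b));
    return rcpp_result_gen;
END_RCPP
}

NumericMatrix shared_kmer_matrix_cpp(CharacterVector seqs, int k);
RcppExport SEXP _mucintr_shared_kmer_matrix_cpp(SEXP seqsSEXP, SEXP kSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< CharacterVector >::type seqs(seqsSEXP);
    Rcpp::traits::input_parameter< int >::type k(kSEXP);
    rcpp_result_gen = Rcpp::wrap(shared_kmer_matrix_cpp(seqs, k));
    return rcpp_result_gen;
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
    {"_mucintr_nw_align_cpp", (DL_FUNC) &_mucintr_nw_align_cpp, 10},
    {"_mucintr_push_gaps_right_cpp", (DL_FUNC) &_mucintr_push_gaps_right_cpp, 2},
    {"_mucintr_shared_kmer_matrix_cpp", (DL_FUNC) &_mucintr_shared_kmer_matrix_cpp, 2},
    {NULL, NULL, 0}
};

RcppExport void R_init_mucintr(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
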