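// Inverted-index candidate-vs-spectra matching core.
//
// One call scores a chunk of candidate modified peptides against every
// spectrum reachable through the index and folds the results into the
// running per-spectrum best-PSM state (updated in place). All reductions
// that the R reference matcher performs with sum()/cumsum() are accumulated
// in long double here so the two paths agree bit for bit.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

namespace {

struct XcorrView {
  const int *bins;
  const double *prefix;  // length len + 1
  const double *vals;
  int len;

  // y'(q) = y(q) - (1/151) * sum_{|tau| <= 75} y(q + tau)
  double eval(int q, int half_window) const {
    const int *b0 = bins, *b1 = bins + len;
    const int *lo = std::lower_bound(b0, b1, q - half_window);
    const int *hi = std::upper_bound(b0, b1, q + half_window);
    double s = prefix[hi - b0] - prefix[lo - b0];
    const int *p = std::lower_bound(b0, b1, q);
    double v = (p != b1 && *p == q) ? vals[p - b0] : 0.0;
    return v - s / 151.0;
  }
};

inline bool charge_allowed(int ion_z, int prec_z) {
  return ion_z == 1 || prec_z >= ion_z;
}

}  // namespace

// Returns the per-candidate best PSM for the chunk (one entry per
// candidate; spectrum slot -1 when the candidate matched nothing), and
// updates the per-spectrum best state in place.
// [[Rcpp::export]]
List search_chunk_cpp(IntegerVector idx_bins, IntegerVector idx_start,
                      IntegerVector post_row, NumericVector post_int,
                      NumericVector prec_mass, IntegerVector prec_charge,
                      IntegerVector xc_start, IntegerVector xcp_start,
                      IntegerVector xc_bins, NumericVector xc_vals,
                      NumericVector xc_prefix,
                      CharacterVector seqs, IntegerVector pep_row,
                      IntegerVector n_varmods, IntegerVector cand_decoy,
                      CharacterVector pepkey,
                      NumericVector deltas, IntegerVector delta_start,
                      NumericVector aa_mass_26,
                      double bin_width, double bin_offset,
                      double proton, double water,
                      IntegerVector frag_charges,
                      int min_matched, double dm_lo, double dm_hi,
                      double narrow_ppm, int half_window,
                      NumericVector lfact,
                      NumericVector best_H, NumericVector best_X,
                      NumericVector best_sIb, NumericVector best_sIy,
                      NumericVector best_mass, NumericVector best_dm,
                      IntegerVector best_Nb, IntegerVector best_Ny,
                      IntegerVector best_pep_row, IntegerVector best_nvm,
                      IntegerVector best_decoy, CharacterVector best_key) {
  const int n_spectra = prec_mass.size();
  const int n_cand = seqs.size();
  const int n_idx_bins = idx_bins.size();
  const int nz = frag_charges.size();

  std::vector<XcorrView> xv(n_spectra);
  for (int s = 0; s < n_spectra; ++s) {
    xv[s].bins = &xc_bins[0] + xc_start[s];
    xv[s].vals = &xc_vals[0] + xc_start[s];
    xv[s].prefix = &xc_prefix[0] + xcp_start[s];
    xv[s].len = xc_start[s + 1] - xc_start[s];
  }

  std::vector<int> nb(n_spectra, 0), ny(n_spectra, 0);
  std::vector<long double> sib(n_spectra, 0.0L), siy(n_spectra, 0.0L);
  std::vector<char> touched(n_spectra, 0);
  std::vector<int> touch_list;
  touch_list.reserve(256);

  std::vector<double> res_mass, bsum, ysum;
  std::vector<int> ion_bin, ion_z;
  std::vector<char> ion_is_b;

  // per-candidate best PSM (the per-peptide stream used by validation)
  NumericVector cb_H(n_cand, NA_REAL), cb_X(n_cand), cb_sIb(n_cand),
      cb_sIy(n_cand), cb_mass(n_cand), cb_dm(n_cand);
  IntegerVector cb_Nb(n_cand), cb_Ny(n_cand), cb_spec(n_cand, -1);

  const int *ib = idx_bins.begin();

  for (int c = 0; c < n_cand; ++c) {
    const char *sq = CHAR(STRING_ELT(seqs, c));
    const int L = (int)std::strlen(sq);
    if (L < 2) continue;
    const double *dl = &deltas[0] + delta_start[c];

    res_mass.resize(L);
    long double acc = 0.0L;
    for (int i = 0; i < L; ++i) {
      res_mass[i] = aa_mass_26[sq[i] - 'A'] + dl[i];
      acc += res_mass[i];
    }
    const double cand_mass = (double)acc + water;

    // cumulative prefix/suffix residue masses, long double like R cumsum()
    bsum.resize(L - 1);
    ysum.resize(L - 1);
    acc = 0.0L;
    for (int i = 0; i < L - 1; ++i) { acc += res_mass[i]; bsum[i] = (double)acc; }
    acc = 0.0L;
    for (int j = 0; j < L - 1; ++j) { acc += res_mass[L - 1 - j]; ysum[j] = (double)acc; }

    // canonical ion order: all b (per charge, ascending i), then all y
    ion_bin.clear(); ion_z.clear(); ion_is_b.clear();
    for (int zi = 0; zi < nz; ++zi) {
      const double z = frag_charges[zi];
      for (int i = 0; i < L - 1; ++i) {
        double mz = (bsum[i] + z * proton) / z;
        ion_bin.push_back((int)std::floor((mz - bin_offset) / bin_width));
        ion_z.push_back(frag_charges[zi]);
        ion_is_b.push_back(1);
      }
    }
    for (int zi = 0; zi < nz; ++zi) {
      const double z = frag_charges[zi];
      for (int j = 0; j < L - 1; ++j) {
        double mz = (ysum[j] + water + z * proton) / z;
        ion_bin.push_back((int)std::floor((mz - bin_offset) / bin_width));
        ion_z.push_back(frag_charges[zi]);
        ion_is_b.push_back(0);
      }
    }
    const int n_ions = (int)ion_bin.size();

    // accumulate matches through the index
    for (int k = 0; k < n_ions; ++k) {
      const int q = ion_bin[k];
      const int *pos = std::lower_bound(ib, ib + n_idx_bins, q);
      if (pos == ib + n_idx_bins || *pos != q) continue;
      const int bi = (int)(pos - ib);
      for (int p = idx_start[bi]; p < idx_start[bi + 1]; ++p) {
        const int row = post_row[p];
        if (!charge_allowed(ion_z[k], prec_charge[row])) continue;
        if (!touched[row]) {
          touched[row] = 1;
          touch_list.push_back(row);
          nb[row] = 0; ny[row] = 0; sib[row] = 0.0L; siy[row] = 0.0L;
        }
        if (ion_is_b[k]) { nb[row] += 1; sib[row] += post_int[p]; }
        else             { ny[row] += 1; siy[row] += post_int[p]; }
      }
    }

    // score survivors and fold into the running best state
    std::sort(touch_list.begin(), touch_list.end());
    for (size_t t = 0; t < touch_list.size(); ++t) {
      const int row = touch_list[t];
      touched[row] = 0;
      const int Nb = nb[row], Ny = ny[row];
      if (Nb + Ny < min_matched) continue;
      const double dm = prec_mass[row] - cand_mass;
      if (dm < dm_lo || dm > dm_hi) continue;
      if (narrow_ppm > 0 && std::abs(dm) / cand_mass * 1e6 > narrow_ppm) continue;
      const double sIb = (double)sib[row], sIy = (double)siy[row];
      const double H = lfact[Nb] + lfact[Ny] +
        std::log(sIb > 1 ? sIb : 1.0) + std::log(sIy > 1 ? sIy : 1.0);

      // X only decides ties / winners; a pair strictly below both running
      // bests on H can never be stored, so skip the xcorr evaluation
      const bool may_win_spec = R_IsNA(best_H[row]) || H >= best_H[row];
      const bool may_win_cand = R_IsNA(cb_H[c]) || H >= cb_H[c];
      if (!may_win_spec && !may_win_cand) continue;
      long double xacc = 0.0L;
      for (int k = 0; k < n_ions; ++k) {
        if (!charge_allowed(ion_z[k], prec_charge[row])) continue;
        xacc += xv[row].eval(ion_bin[k], half_window);
      }
      const double X = (double)xacc;

      bool better;
      if (R_IsNA(best_H[row]) || H > best_H[row]) better = true;
      else if (H < best_H[row]) better = false;
      else if (X != best_X[row]) better = X > best_X[row];
      else {
        const int cmp = std::strcmp(CHAR(STRING_ELT(pepkey, c)),
                                    CHAR(STRING_ELT(best_key, row)));
        if (cmp != 0) better = cmp < 0;
        else better = cand_decoy[c] < best_decoy[row];
      }
      if (better) {
        best_H[row] = H; best_X[row] = X;
        best_sIb[row] = sIb; best_sIy[row] = sIy;
        best_Nb[row] = Nb; best_Ny[row] = Ny;
        best_mass[row] = cand_mass; best_dm[row] = dm;
        best_pep_row[row] = pep_row[c]; best_nvm[row] = n_varmods[c];
        best_decoy[row] = cand_decoy[c];
        SET_STRING_ELT(best_key, row, STRING_ELT(pepkey, c));
      }

      // per-candidate best spectrum: max H, then max X, then smaller row
      bool cbetter;
      if (R_IsNA(cb_H[c]) || H > cb_H[c]) cbetter = true;
      else if (H < cb_H[c]) cbetter = false;
      else if (X != cb_X[c]) cbetter = X > cb_X[c];
      else cbetter = false;  // rows scanned ascending: keep the first
      if (cbetter) {
        cb_H[c] = H; cb_X[c] = X; cb_sIb[c] = sIb; cb_sIy[c] = sIy;
        cb_Nb[c] = Nb; cb_Ny[c] = Ny; cb_mass[c] = cand_mass;
        cb_dm[c] = dm; cb_spec[c] = row;
      }
    }
    touch_list.clear();
  }

  return List::create(
      Named("H") = cb_H, Named("X") = cb_X, Named("sIb") = cb_sIb,
      Named("sIy") = cb_sIy, Named("mass") = cb_mass, Named("dm") = cb_dm,
      Named("Nb") = cb_Nb, Named("Ny") = cb_Ny, Named("spec_row") = cb_spec);
}
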