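#include <Rcpp.h>
using namespace Rcpp;

// Gene scan plus binding-graph construction for one genome, the per-birth
// hot path (every offspring carries a freshly mutated genome that must be
// rescanned and rewired). Semantics identical to the R reference
// (scan_codes() + genome_tables_r() in R/genome.R, R/grn.R), which the test
// suite holds it to.
//
// Chromosomes arrive as raw vectors of digit values < k. `mm` is the
// k^lb x k^lb complement-mismatch table between binding codes.
// [[Rcpp::export(name = ".scan_tables_cpp")]]
List scan_tables_cpp(List chroms, IntegerVector promoter, int type_len,
                     int binding_len, int payload_len, int k, int tol,
                     IntegerMatrix mm, IntegerVector chan_codes,
                     int n_actuators) {
  const int np = promoter.size();
  const int gene_len = np + type_len + binding_len + payload_len;
  std::vector<int> chrom, start, kind, mode, actu, sig, site;
  std::vector<double> value;

  for (int ci = 0; ci < chroms.size(); ++ci) {
    RawVector v = chroms[ci];
    const int n = v.size();
    int pos = 0;
    while (pos + gene_len <= n) {
      bool hit = true;
      for (int j = 0; j < np; ++j) {
        if ((int)v[pos + j] != promoter[j]) { hit = false; break; }
      }
      if (!hit) { ++pos; continue; }
      // decode fields
      int off = pos + np;
      long tcode = 0;
      for (int j = 0; j < type_len; ++j) tcode = tcode * k + v[off + j];
      off += type_len;
      int scode = 0;
      for (int j = 0; j < binding_len; ++j) scode = scode * k + v[off + j];
      off += binding_len;
      int gcode = 0;
      for (int j = 0; j < binding_len; ++j) gcode = gcode * k + v[off + j];
      int e1 = v[off + binding_len], e2 = v[off + binding_len + 1];
      int e3 = v[off + binding_len + 2], e4 = v[off + binding_len + 3];
      int ty = (int)(tcode % 3);
      chrom.push_back(ci + 1);
      start.push_back(pos + 1);
      kind.push_back(ty);
      site.push_back(scode);
      sig.push_back(gcode);
      mode.push_back(ty == 1 ? e1 % 2 : 0);
      actu.push_back(ty == 2 ? (k * e1 + e2) % n_actuators + 1 : 0);
      value.push_back(ty == 2 && 2 * (k * e3 + e4) >= k * k ? 1.0 : 0.0);
      pos += gene_len;  // first promoter wins; resume after the gene
    }
  }

  const int n = (int)start.size();
  // channel -> matching signalling loci
  std::vector<int> chan_ptr(chan_codes.size() + 1, 0), chan_tgt;
  std::vector<double> chan_q;
  for (int c = 0; c < chan_codes.size(); ++c) {
    for (int t = 0; t < n; ++t) {
      if (kind[t] != 0) continue;
      int d = mm(chan_codes[c], site[t]);
      if (d <= tol) {
        chan_tgt.push_back(t + 1);
        chan_q.push_back(double(binding_len - d) / binding_len);
      }
    }
    chan_ptr[c + 1] = (int)chan_tgt.size();
  }
  // agent signature -> target loci (structural products do not bind)
  std::vector<int> adj_ptr(n + 1, 0), adj_tgt;
  std::vector<double> adj_q;
  for (int i = 0; i < n; ++i) {
    if (kind[i] != 2) {
      const int* row = &mm(sig[i], 0);
      const int stride = mm.nrow();
      for (int t = 0; t < n; ++t) {
        int d = row[(size_t)site[t] * stride];
        if (d <= tol) {
          adj_tgt.push_back(t + 1);
          adj_q.push_back(double(binding_len - d) / binding_len);
        }
      }
    }
    adj_ptr[i + 1] = (int)adj_tgt.size();
  }
  return List::create(
      _["n_loci"] = n, _["kind"] = wrap(kind), _["mode"] = wrap(mode),
      _["actuator"] = wrap(actu), _["value"] = wrap(value),
      _["chan_ptr"] = wrap(chan_ptr), _["chan_tgt"] = wrap(chan_tgt),
      _["chan_q"] = wrap(chan_q), _["adj_ptr"] = wrap(adj_ptr),
      _["adj_tgt"] = wrap(adj_tgt), _["adj_q"] = wrap(adj_q),
      _["chromosome"] = wrap(chrom), _["start"] = wrap(start),
      _["sig_code"] = wrap(sig), _["site_code"] = wrap(site));
}
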