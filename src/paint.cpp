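#include <Rcpp.h>
using namespace Rcpp;

// Forward-in-time chromosome painting under a time-varying migration history.
//
// The population is a set of n_pop haploid chromosomes. It is founded at the
// oldest generation entirely from migrants; at each later generation every
// haploid is a recombinant (Poisson crossovers per Morgan, no interference)
// of two random parental haploids, after which a fraction of haploids is
// replaced by fresh single-ancestry migrant chromosomes. A migrant entering
// t generations before present therefore undergoes t - 1 meioses, matching
// the analytic tract model. Chromosomes are painted independently.

namespace {

struct Hap {
  std::vector<double> ends;    // segment right endpoints, last == L
  std::vector<int> lab;        // ancestry code per segment
};

inline void push_seg(Hap &h, double end, int lab) {
  if (!h.lab.empty() && h.lab.back() == lab)
    h.ends.back() = end;
  else {
    h.ends.push_back(end);
    h.lab.push_back(lab);
  }
}

// recombine parents a, b with crossovers at xs (sorted), starting on a or b
Hap recombine(const Hap &a, const Hap &b, const std::vector<double> &xs,
              bool first_a, double L) {
  Hap out;
  out.ends.reserve(a.ends.size() + b.ends.size() + xs.size());
  out.lab.reserve(a.ends.size() + b.ends.size() + xs.size());
  const Hap *cur = first_a ? &a : &b;
  const Hap *oth = first_a ? &b : &a;
  double pos = 0.0;
  for (size_t k = 0; k <= xs.size(); ++k) {
    double stop = (k == xs.size()) ? L : xs[k];
    if (stop > pos) {
      size_t i = 0;
      while (i < cur->ends.size() && cur->ends[i] <= pos) ++i;
      for (; i < cur->ends.size() && pos < stop; ++i) {
        double e = std::min(cur->ends[i], stop);
        push_seg(out, e, cur->lab[i]);
        pos = e;
      }
      pos = stop;
    }
    std::swap(cur, oth);
  }
  out.ends.back() = L;
  return out;
}

int sample_ancestry(const double *w, int k, double tot) {
  double u = unif_rand() * tot, c = 0.0;
  for (int j = 0; j < k; ++j) { c += w[j]; if (u <= c) return j; }
  return k - 1;
}

}  // namespace

// gens: generation index per migration row, decreasing, oldest (founding) first
// mig:  rows aligned with gens, columns = ancestries, founding row sums to 1
// [[Rcpp::export(name = ".paint_genome")]]
List paint_genome(NumericVector chrom_len, IntegerVector gens,
                  NumericMatrix mig, int n_pop, int n_out) {
  RNGScope scope;
  const int K = mig.ncol();
  const int T0 = gens[0];
  std::vector<double> Mtot(T0 + 1, 0.0);           // total inflow by generation
  std::vector<std::vector<double>> rows(T0 + 1, std::vector<double>(K, 0.0));
  for (int r = 0; r < gens.size(); ++r) {
    int g = gens[r];
    for (int j = 0; j < K; ++j) { rows[g][j] = mig(r, j); Mtot[g] += mig(r, j); }
  }
  std::vector<int> out_chrom, out_hap, out_lab;
  std::vector<double> out_start, out_end;

  for (int c = 0; c < chrom_len.size(); ++c) {
    const double L = chrom_len[c];
    std::vector<Hap> pop(n_pop), nxt(n_pop);
    for (int i = 0; i < n_pop; ++i) {             // founding generation
      int a = sample_ancestry(rows[T0].data(), K, Mtot[T0]);
      pop[i].ends.assign(1, L);
      pop[i].lab.assign(1, a);
    }
    for (int g = T0 - 1; g >= 1; --g) {
      for (int i = 0; i < n_pop; ++i) {
        int p1 = (int)(unif_rand() * n_pop) % n_pop;
        int p2 = (int)(unif_rand() * n_pop) % n_pop;
        if (p2 == p1) p2 = (p1 + 1) % n_pop;
        int k = (int)R::rpois(L);
        if (k == 0) {
          nxt[i] = pop[unif_rand() < 0.5 ? p1 : p2];
        } else {
          std::vector<double> xs(k);
          for (int q = 0; q < k; ++q) xs[q] = unif_rand() * L;
          std::sort(xs.begin(), xs.end());
          nxt[i] = recombine(pop[p1], pop[p2], xs, unif_rand() < 0.5, L);
        }
      }
      std::swap(pop, nxt);
      if (g >= 2 && Mtot[g] > 0) {                // replacement by migrants
        for (int i = 0; i < n_pop; ++i) {
          if (unif_rand() < Mtot[g]) {
            int a = sample_ancestry(rows[g].data(), K, Mtot[g]);
            pop[i].ends.assign(1, L);
            pop[i].lab.assign(1, a);
          }
        }
      }
    }
    for (int i = 0; i < n_out; ++i) {             // emit sampled haploids
      double s = 0.0;
      for (size_t j = 0; j < pop[i].ends.size(); ++j) {
        out_chrom.push_back(c + 1);
        out_hap.push_back(i + 1);
        out_start.push_back(s);
        out_end.push_back(pop[i].ends[j]);
        out_lab.push_back(pop[i].lab[j] + 1);
        s = pop[i].ends[j];
      }
    }
  }
  return List::create(_["chrom"] = wrap(out_chrom), _["hap"] = wrap(out_hap),
                      _["start"] = wrap(out_start), _["end"] = wrap(out_end),
                      _["ancestry"] = wrap(out_lab));
}
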