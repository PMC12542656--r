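// de Bruijn graph kernels: canonical k-mer counting, unitig compaction
// with count-1 side-path clipping, and shared-k-mer candidate pairing for
// consensus merging.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

inline std::string rc(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp(c);
  return out;
}

inline std::string canon(const std::string& s) {
  std::string r = rc(s);
  return (s <= r) ? s : r;
}

inline bool has_n(const std::string& s) {
  return s.find_first_not_of("ACGT") != std::string::npos;
}

typedef std::unordered_map<std::string, int> KmerMap;

KmerMap count_kmers(const std::vector<std::string>& seqs, int k) {
  KmerMap counts;
  for (const auto& s : seqs) {
    if ((int)s.size() < k) continue;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      std::string km = s.substr(i, k);
      if (has_n(km)) continue;
      counts[canon(km)]++;
    }
  }
  return counts;
}

struct Unitig {
  std::string seq;
  double mean_cov;
  int max_count;
  bool attached;   // meets the graph at >= 1 extremity
  bool bridge;     // meets the graph at both extremities
  int alt_support; // strongest parallel branch at its junction(s)
};

// oriented successor candidates of an oriented k-mer
inline int count_ext(const std::string& om, const KmerMap& counts, int k,
                     std::string* unique_succ) {
  std::string suf = om.substr(1);
  int n = 0;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (char b : bases) {
    std::string cand = suf + b;
    if (counts.count(canon(cand))) {
      ++n;
      if (unique_succ) *unique_succ = cand;
    }
  }
  return n;
}

inline int count_in(const std::string& om, const KmerMap& counts, int k) {
  // predecessors of om = successors of rc(om)
  return count_ext(rc(om), counts, k, nullptr);
}

// strongest sibling branch competing with oriented k-mer `om` at its head
// junction: other successors of om's predecessors
int head_sibling_support(const std::string& om, const KmerMap& counts,
                         int k) {
  int best = 0;
  std::string pre = om.substr(0, k - 1);
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (char b : bases) {
    std::string pred = std::string(1, b) + pre;
    if (!counts.count(canon(pred))) continue;
    std::string suf = pred.substr(1);
    for (char c : bases) {
      std::string sib = suf + c;
      if (sib == om) continue;
      auto it = counts.find(canon(sib));
      if (it != counts.end() && it->second > best) best = it->second;
    }
  }
  return best;
}

std::vector<Unitig> compact(const KmerMap& counts, int k) {
  std::vector<Unitig> out;
  std::unordered_set<std::string> visited; // canonical forms consumed
  // an oriented kmer starts a unitig if it has no unique valid predecessor
  auto valid_succ = [&](const std::string& om, std::string* nxt) {
    std::string cand;
    if (count_ext(om, counts, k, &cand) != 1) return false;
    if (count_in(cand, counts, k) != 1) return false;
    if (nxt) *nxt = cand;
    return true;
  };
  std::vector<std::string> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end()); // deterministic order
  auto emit = [&](const std::string& start) {
    std::string cur = start;
    std::string seq = start;
    double tot = 0; int nk = 0, maxc = 0;
    while (true) {
      std::string c = canon(cur);
      visited.insert(c);
      int cnt = counts.at(c);
      tot += cnt; ++nk; if (cnt > maxc) maxc = cnt;
      std::string nxt;
      if (!valid_succ(cur, &nxt)) break;
      if (visited.count(canon(nxt))) break;
      seq.push_back(nxt.back());
      cur = nxt;
    }
    Unitig u;
    u.mean_cov = tot / nk;
    u.max_count = maxc;
    // attached where it meets the rest of the graph at either extremity
    bool head = count_in(start, counts, k) > 0;
    bool tail = count_ext(cur, counts, k, nullptr) > 0;
    u.attached = head || tail;
    u.bridge = head && tail;
    int ha = head ? head_sibling_support(start, counts, k) : 0;
    int ta = tail ? head_sibling_support(rc(cur), counts, k) : 0;
    if (u.bridge) u.alt_support = std::min(ha, ta);
    else u.alt_support = std::max(ha, ta);
    std::string r = rc(seq);
    u.seq = (seq <= r) ? seq : r;
    out.push_back(u);
  };
  for (const auto& km : keys) {
    for (const std::string& om : {km, rc(km)}) {
      if (visited.count(km)) break;
      // start iff no valid incoming pointer: predecessor absent, branching,
      // or this node has in-degree != 1
      bool is_start = false;
      int ind = count_in(om, counts, k);
      if (ind != 1) {
        is_start = true;
      } else {
        std::string pred_rc; // unique predecessor = rc(succ of rc(om))
        std::string cand;
        count_ext(rc(om), counts, k, &cand); // ind==1 so unique
        std::string pred = rc(cand);
        std::string tmp;
        if (!valid_succ(pred, &tmp) || tmp != om) is_start = true;
      }
      if (is_start) emit(om);
    }
  }
  // cycles with no start
  for (const auto& km : keys) {
    if (!visited.count(km)) emit(km);
  }
  // deduplicate canonical sequences (linear unitigs can emerge twice)
  std::unordered_set<std::string> seen;
  std::vector<Unitig> ded;
  for (auto& u : out) {
    if (seen.insert(u.seq).second) ded.push_back(u);
  }
  return ded;
}

} // namespace

// [[Rcpp::export(name = ".cpp_kmer_counts")]]
List cpp_kmer_counts(std::vector<std::string> seqs, int k) {
  KmerMap counts = count_kmers(seqs, k);
  std::vector<std::string> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector cnt(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) cnt[i] = counts[keys[i]];
  return List::create(_["kmer"] = wrap(keys), _["count"] = cnt);
}

// [[Rcpp::export(name = ".cpp_unitigs")]]
DataFrame cpp_unitigs(std::vector<std::string> kmers, IntegerVector count,
                      int k, double tip_len_factor, bool clip,
                      double max_artifact_len) {
  KmerMap counts;
  for (size_t i = 0; i < kmers.size(); ++i) counts[kmers[i]] = count[i];
  std::vector<Unitig> u = compact(counts, k);
  if (clip) {
    for (int round = 0; round < 8; ++round) {
      std::vector<const Unitig*> bad;
      for (auto& x : u) {
        if (!x.attached) continue;
        // tips hang off one junction; weak bridges run in parallel to
        // better-supported sequence and may be longer (multi-error arms).
        // A side path is clipped only when a parallel branch carries at
        // least four times its support, so balanced variant bubbles and
        // genuinely low-coverage dead ends are kept.
        // error artifacts are bounded by the read length: end errors make
        // tips up to ~read length, multi-error arms bridges up to ~read
        // length + k
        double lim = x.bridge
          ? std::max(4.0 * k, max_artifact_len + k)
          : std::max(tip_len_factor * k, max_artifact_len);
        bool weak = x.max_count == 1 ||
          (x.alt_support >= 2 && x.alt_support >= 4 * x.max_count);
        if (weak && (double)x.seq.size() < lim) bad.push_back(&x);
      }
      if (bad.empty() || bad.size() == u.size()) break;
      for (auto* x : bad) {
        for (size_t i = 0; i + k <= x->seq.size(); ++i) {
          counts.erase(canon(x->seq.substr(i, k)));
        }
      }
      u = compact(counts, k);
      if (u.empty()) break;
    }
  }
  CharacterVector seq(u.size());
  NumericVector cov(u.size());
  IntegerVector maxc(u.size()), alt(u.size());
  LogicalVector att(u.size()), brg(u.size());
  for (size_t i = 0; i < u.size(); ++i) {
    seq[i] = u[i].seq; cov[i] = u[i].mean_cov;
    maxc[i] = u[i].max_count; att[i] = u[i].attached;
    brg[i] = u[i].bridge; alt[i] = u[i].alt_support;
  }
  return DataFrame::create(_["sequence"] = seq, _["mean_coverage"] = cov,
                           _["max_count"] = maxc, _["attached"] = att,
                           _["bridge"] = brg, _["alt_support"] = alt,
                           _["stringsAsFactors"] = false);
}

// For each sequence i, the indices j < i (1-based) sharing at least one
// canonical k-mer — the candidate containment pairs of consensus merging.
// [[Rcpp::export(name = ".cpp_candidate_pairs")]]
List cpp_candidate_pairs(std::vector<std::string> seqs, int k) {
  std::unordered_map<std::string, std::vector<int>> where;
  List out(seqs.size());
  for (size_t i = 0; i < seqs.size(); ++i) {
    std::unordered_set<int> cand;
    std::unordered_set<std::string> mine;
    if ((int)seqs[i].size() >= k) {
      for (size_t p = 0; p + k <= seqs[i].size(); ++p) {
        std::string km = seqs[i].substr(p, k);
        if (has_n(km)) continue;
        km = canon(km);
        if (!mine.insert(km).second) continue;
        auto it = where.find(km);
        if (it != where.end()) {
          for (int j : it->second) cand.insert(j);
        }
        where[km].push_back((int)i + 1);
      }
    }
    std::vector<int> v(cand.begin(), cand.end());
    std::sort(v.begin(), v.end());
    out[i] = wrap(v);
  }
  return out;
}
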