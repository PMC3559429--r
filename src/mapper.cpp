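// Seed-and-extend ungapped read mapper over a transcriptome.
//
// Index: exact k-mer -> (transcript, offset) for every forward position
// (k-mers containing non-ACGT are skipped). Queries look up every k-mer of
// the read and of its reverse complement (stride 1), turn hits into
// candidate (transcript, start, strand) diagonals, score each candidate by
// full-length Hamming distance, and accept the minimum iff it is within the
// mismatch budget. With stride-1 seeding, a read with d mismatches at its
// true locus is guaranteed a seed hit whenever k <= ceil((L - d) / (d + 1)).

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

struct RefIndex {
  int k;
  std::vector<std::string> seq;
  std::vector<int> gene;       // gene index per transcript
  std::vector<int> rank;       // lexicographic rank of transcript id
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > tab;
};

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': case 'a': r[i] = 'T'; break;
    case 'C': case 'c': r[i] = 'G'; break;
    case 'G': case 'g': r[i] = 'C'; break;
    case 'T': case 't': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(CharacterVector seqs, IntegerVector gene,
                     IntegerVector rank, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  RefIndex *idx = new RefIndex();
  idx->k = k;
  idx->seq.reserve(seqs.size());
  for (int t = 0; t < seqs.size(); ++t) {
    idx->seq.push_back(as<std::string>(seqs[t]));
    idx->gene.push_back(gene[t]);
    idx->rank.push_back(rank[t]);
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t t = 0; t < idx->seq.size(); ++t) {
    const std::string &s = idx->seq[t];
    if ((int)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;  // run length of valid bases ending here
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base2code(s[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k)
        idx->tab[key].push_back(std::make_pair((int)t, (int)(i + 1 - k)));
    }
  }
  XPtr<RefIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".index_stats_cpp")]]
List index_stats_cpp(SEXP xp) {
  XPtr<RefIndex> idx(xp);
  size_t nkmer = idx->tab.size(), npos = 0;
  for (std::unordered_map<uint64_t,
         std::vector<std::pair<int, int> > >::const_iterator
         it = idx->tab.begin(); it != idx->tab.end(); ++it)
    npos += it->second.size();
  return List::create(_["k"] = idx->k,
                      _["n_kmers"] = (double)nkmer,
                      _["n_positions"] = (double)npos);
}

// [[Rcpp::export(name = ".index_lookup_cpp")]]
DataFrame index_lookup_cpp(SEXP xp, std::string kmer) {
  XPtr<RefIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("kmer length must equal index k");
  uint64_t key = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base2code(kmer[i]);
    if (c < 0) return DataFrame::create(_["transcript"] = IntegerVector(0),
                                        _["pos"] = IntegerVector(0));
    key = (key << 2) | (uint64_t)c;
  }
  std::unordered_map<uint64_t,
    std::vector<std::pair<int, int> > >::const_iterator it =
    idx->tab.find(key);
  if (it == idx->tab.end())
    return DataFrame::create(_["transcript"] = IntegerVector(0),
                             _["pos"] = IntegerVector(0));
  int n = it->second.size();
  IntegerVector tx(n), pos(n);
  for (int i = 0; i < n; ++i) {
    tx[i] = it->second[i].first + 1;  // 1-based transcript index
    pos[i] = it->second[i].second;    // 0-based offset
  }
  return DataFrame::create(_["transcript"] = tx, _["pos"] = pos);
}

struct Cand { int tx, start, strand; };

// status: 0 unmapped, 1 mapped, 2 ambiguous (ties across distinct genes)
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(SEXP xp, CharacterVector reads, IntegerVector budget,
                   int first_best) {
  XPtr<RefIndex> idx(xp);
  const int k = idx->k;
  int n = reads.size();
  IntegerVector status(n), tx(n), pos(n), mm(n);
  CharacterVector strand(n);

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = fwd.size();
    status[r] = 0; tx[r] = NA_INTEGER; pos[r] = NA_INTEGER;
    mm[r] = NA_INTEGER; strand[r] = NA_STRING;
    if (L < k) continue;
    std::string rev = revcomp(fwd);
    const std::string *sr[2] = { &fwd, &rev };
    const uint64_t mask = (1ULL << (2 * k)) - 1;

    std::vector<Cand> cands;
    for (int st = 0; st < 2; ++st) {
      const std::string &s = *sr[st];
      uint64_t key = 0;
      int valid = 0;
      for (int i = 0; i < L; ++i) {
        int c = base2code(s[i]);
        if (c < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++valid < k) continue;
        int off = i + 1 - k;
        std::unordered_map<uint64_t,
          std::vector<std::pair<int, int> > >::const_iterator it =
          idx->tab.find(key);
        if (it == idx->tab.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int t = it->second[h].first;
          int start = it->second[h].second - off;
          if (start < 0 || start + L > (int)idx->seq[t].size()) continue;
          Cand cd; cd.tx = t; cd.start = start; cd.strand = st;
          cands.push_back(cd);
        }
      }
    }
    if (cands.empty()) continue;

    // dedupe and score; keep every candidate achieving the running minimum
    std::sort(cands.begin(), cands.end(),
              [](const Cand &a, const Cand &b) {
                if (a.tx != b.tx) return a.tx < b.tx;
                if (a.start != b.start) return a.start < b.start;
                return a.strand < b.strand;
              });
    int best = INT_MAX;
    std::vector<std::pair<Cand, int> > hits;
    for (size_t c = 0; c < cands.size(); ++c) {
      if (c > 0 && cands[c].tx == cands[c - 1].tx &&
          cands[c].start == cands[c - 1].start &&
          cands[c].strand == cands[c - 1].strand) continue;
      const std::string &s = *sr[cands[c].strand];
      const std::string &t = idx->seq[cands[c].tx];
      int d = 0, lim = best;  // early abandon just past current best
      for (int i = 0; i < L; ++i) {
        if (s[i] != t[cands[c].start + i] && ++d > lim) break;
      }
      if (d < best) { best = d; hits.clear(); }
      if (d == best) hits.push_back(std::make_pair(cands[c], d));
    }
    if (best > budget[r]) continue;

    bool multi_gene = false;
    for (size_t h = 1; h < hits.size(); ++h)
      if (idx->gene[hits[h].first.tx] != idx->gene[hits[0].first.tx])
        multi_gene = true;
    if (multi_gene && !first_best) { status[r] = 2; continue; }

    // deterministic pick: lexicographic transcript id, then position, + first
    size_t pick = 0;
    for (size_t h = 1; h < hits.size(); ++h) {
      const Cand &a = hits[h].first, &b = hits[pick].first;
      int ra = idx->rank[a.tx], rb = idx->rank[b.tx];
      if (ra < rb || (ra == rb && a.start < b.start) ||
          (ra == rb && a.start == b.start && a.strand < b.strand))
        pick = h;
    }
    status[r] = 1;
    tx[r] = hits[pick].first.tx + 1;
    pos[r] = hits[pick].first.start;
    strand[r] = hits[pick].first.strand == 0 ? "+" : "-";
    mm[r] = best;
  }
  return List::create(_["status"] = status, _["tx"] = tx, _["pos"] = pos,
                      _["strand"] = strand, _["mismatches"] = mm);
}
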