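// Core of the selective-alignment pipeline: unitig index construction over a
// compacted de Bruijn graph, uni-MEM collection, anchor projection/compaction,
// minimap2-style chaining, score-only extension alignment, paired-end merging,
// and the decoy-aware fragment classifier. All phases are exposed individually
// to R; the batch runner composes the same internal routines.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <array>
#include <functional>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// nucleotide / k-mer helpers
// ---------------------------------------------------------------------------

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char compBase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcompStr(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = compBase(c);
  return r;
}

// encode k-mer starting at position i; returns false if any non-ACGT base
static inline bool encodeKmer(const std::string& s, size_t i, int k,
                              uint64_t& fwd, uint64_t& rc) {
  fwd = 0; rc = 0;
  for (int j = 0; j < k; ++j) {
    int b = base2bits(s[i + j]);
    if (b < 0) return false;
    fwd = (fwd << 2) | (uint64_t)b;
    rc |= ((uint64_t)(3 - b)) << (2 * j);
  }
  return true;
}

// ---------------------------------------------------------------------------
// index construction: compacted de Bruijn graph over the reference catalog
// ---------------------------------------------------------------------------

struct ExtMask { uint8_t left = 0, right = 0; };  // bits 0..3 bases, bit 4 boundary

struct KmerLoc { uint32_t uid; uint32_t off; };

struct UnitigSet {
  int k = 0;
  std::vector<std::string> unitigs;
  // occurrence table, CSR by unitig id
  std::vector<int> occPtr;                 // size n_unitigs + 1
  std::vector<int> occRef, occPos, occStrand;
  std::unordered_map<uint64_t, KmerLoc> kmap;
};

static inline int popcount5(uint8_t m) {
  int c = 0;
  for (int i = 0; i < 5; ++i) if (m & (1 << i)) ++c;
  return c;
}

// N-free segments of a sequence
static void splitSegments(const std::string& s,
                          std::vector<std::pair<size_t, size_t>>& segs) {
  segs.clear();
  size_t n = s.size(), i = 0;
  while (i < n) {
    while (i < n && base2bits(s[i]) < 0) ++i;
    size_t j = i;
    while (j < n && base2bits(s[j]) >= 0) ++j;
    if (j > i) segs.push_back({i, j});
    i = j;
  }
}

static void buildUnitigSet(const std::vector<std::string>& seqs, int k,
                           UnitigSet& us) {
  us.k = k;
  std::unordered_map<uint64_t, ExtMask> ext;
  std::vector<std::pair<size_t, size_t>> segs;

  // pass 1: record extension contexts of every canonical k-mer
  for (const auto& s : seqs) {
    splitSegments(s, segs);
    for (auto& seg : segs) {
      size_t beg = seg.first, end = seg.second;
      if (end - beg < (size_t)k) continue;
      uint64_t fwd, rc;
      encodeKmer(s, beg, k, fwd, rc);
      for (size_t i = beg; i + k <= end; ++i) {
        if (i > beg) {
          int b = base2bits(s[i + k - 1]);
          uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
          fwd = ((fwd << 2) | (uint64_t)b) & mask;
          rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
        }
        bool isFw = fwd <= rc;
        uint64_t canon = isFw ? fwd : rc;
        ExtMask& m = ext[canon];
        uint8_t lb = (i > beg) ? (uint8_t)(1 << base2bits(s[i - 1])) : 0x10;
        uint8_t rb = (i + k < end) ? (uint8_t)(1 << base2bits(s[i + k])) : 0x10;
        if (isFw) {
          m.left |= lb; m.right |= rb;
        } else {
          // canonical is RC of the observed k-mer: neighbors swap & complement
          if (i + k < end)
            m.left |= (uint8_t)(1 << (3 - base2bits(s[i + k])));
          else m.left |= 0x10;
          if (i > beg)
            m.right |= (uint8_t)(1 << (3 - base2bits(s[i - 1])));
          else m.right |= 0x10;
        }
      }
    }
  }

  // pass 2: walk every segment, cut where the graph branches (or at boundaries),
  // emit unitig occurrences, dedupe unitigs by canonical sequence
  std::unordered_map<std::string, uint32_t> useen;
  std::vector<std::vector<int>> occs;  // per uid: flat triples (ref,pos,strand)

  for (size_t r = 0; r < seqs.size(); ++r) {
    const std::string& s = seqs[r];
    splitSegments(s, segs);
    for (auto& seg : segs) {
      size_t beg = seg.first, end = seg.second;
      if (end - beg < (size_t)k) continue;
      size_t nk = end - beg - k + 1;
      // orientation + degrees per k-mer position
      std::vector<uint8_t> outd(nk), ind(nk);
      std::vector<uint64_t> canon(nk);
      uint64_t fwd, rc;
      encodeKmer(s, beg, k, fwd, rc);
      for (size_t i = 0; i < nk; ++i) {
        if (i > 0) {
          int b = base2bits(s[beg + i + k - 1]);
          uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
          fwd = ((fwd << 2) | (uint64_t)b) & mask;
          rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
        }
        bool isFw = fwd <= rc;
        canon[i] = isFw ? fwd : rc;
        const ExtMask& m = ext[canon[i]];
        outd[i] = popcount5(isFw ? m.right : m.left);
        ind[i] = popcount5(isFw ? m.left : m.right);
      }
      size_t i0 = 0;
      while (i0 < nk) {
        size_t i1 = i0;
        // glue while the junction is unbranching; additionally cut where
        // consecutive canonical k-mers coincide (self-reverse-complement
        // repeats would otherwise place one k-mer at two unitig offsets)
        while (i1 + 1 < nk && outd[i1] == 1 && ind[i1 + 1] == 1 &&
               canon[i1] != canon[i1 + 1]) ++i1;
        std::string u = s.substr(beg + i0, (i1 - i0) + k);
        std::string urc = revcompStr(u);
        bool ufw = u <= urc;
        const std::string& canon = ufw ? u : urc;
        uint32_t uid;
        auto it = useen.find(canon);
        if (it == useen.end()) {
          uid = (uint32_t)us.unitigs.size();
          useen.emplace(canon, uid);
          us.unitigs.push_back(canon);
          occs.emplace_back();
        } else uid = it->second;
        occs[uid].push_back((int)r);
        occs[uid].push_back((int)(beg + i0));
        occs[uid].push_back(ufw ? 0 : 1);
        i0 = i1 + 1;
      }
    }
  }

  // CSR occurrence table, occurrences sorted by (ref, pos, strand)
  size_t nu = us.unitigs.size();
  us.occPtr.assign(nu + 1, 0);
  for (size_t u = 0; u < nu; ++u) us.occPtr[u + 1] = us.occPtr[u] + (int)(occs[u].size() / 3);
  us.occRef.resize(us.occPtr[nu]);
  us.occPos.resize(us.occPtr[nu]);
  us.occStrand.resize(us.occPtr[nu]);
  for (size_t u = 0; u < nu; ++u) {
    size_t no = occs[u].size() / 3;
    std::vector<std::array<int, 3>> tmp(no);
    for (size_t j = 0; j < no; ++j)
      tmp[j] = {occs[u][3 * j], occs[u][3 * j + 1], occs[u][3 * j + 2]};
    std::sort(tmp.begin(), tmp.end());
    for (size_t j = 0; j < no; ++j) {
      us.occRef[us.occPtr[u] + j] = tmp[j][0];
      us.occPos[us.occPtr[u] + j] = tmp[j][1];
      us.occStrand[us.occPtr[u] + j] = tmp[j][2];
    }
  }
}

static void buildKmerMap(UnitigSet& us) {
  us.kmap.clear();
  int k = us.k;
  for (uint32_t u = 0; u < us.unitigs.size(); ++u) {
    const std::string& s = us.unitigs[u];
    uint64_t fwd, rc;
    if (s.size() < (size_t)k) continue;
    encodeKmer(s, 0, k, fwd, rc);
    for (size_t i = 0; i + k <= s.size(); ++i) {
      if (i > 0) {
        int b = base2bits(s[i + k - 1]);
        uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      }
      uint64_t canon = std::min(fwd, rc);
      auto it = us.kmap.find(canon);
      if (it == us.kmap.end()) us.kmap.emplace(canon, KmerLoc{u, (uint32_t)i});
      else if (it->second.uid != u || it->second.off != (uint32_t)i)
        stop("k-mer resolves to two unitig positions; this can occur for "
             "palindromic k-mers when k is even - use an odd k");
    }
  }
}

// rebuild a UnitigSet from its R-side representation
static void usFromR(const List& idx, UnitigSet& us) {
  us.k = as<int>(idx["k"]);
  CharacterVector un = idx["unitigs"];
  us.unitigs.assign(un.size(), "");
  for (R_xlen_t i = 0; i < un.size(); ++i) us.unitigs[i] = as<std::string>(un[i]);
  us.occPtr = as<std::vector<int>>(idx["occPtr"]);
  us.occRef = as<std::vector<int>>(idx["occRef"]);
  us.occPos = as<std::vector<int>>(idx["occPos"]);
  us.occStrand = as<std::vector<int>>(idx["occStrand"]);
  buildKmerMap(us);
}

// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, int k) {
  std::vector<std::string> ss(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);
  UnitigSet us;
  buildUnitigSet(ss, k, us);
  buildKmerMap(us);  // validates the one-position-per-k-mer invariant
  return List::create(
    _["k"] = k,
    _["unitigs"] = wrap(us.unitigs),
    _["occPtr"] = wrap(us.occPtr),
    _["occRef"] = wrap(us.occRef),
    _["occPos"] = wrap(us.occPos),
    _["occStrand"] = wrap(us.occStrand));
}

// ---------------------------------------------------------------------------
// phase 1: uni-MEM collection
// ---------------------------------------------------------------------------

struct UniMem { int readStart, len, uid, ustart, orient; };  // orient 0=FW 1=RC

static void collectUniMems(const std::string& read, const UnitigSet& us,
                           std::vector<UniMem>& out) {
  out.clear();
  int k = us.k;
  int n = (int)read.size();
  int p = 0;
  while (p + k <= n) {
    uint64_t fwd, rc;
    if (!encodeKmer(read, p, k, fwd, rc)) { ++p; continue; }
    uint64_t canon = std::min(fwd, rc);
    auto it = us.kmap.find(canon);
    if (it == us.kmap.end()) { ++p; continue; }
    uint32_t uid = it->second.uid, off = it->second.off;
    const std::string& U = us.unitigs[uid];
    bool fwMatch = (read.compare(p, k, U, off, k) == 0);
    int e = 0;
    if (fwMatch) {
      while (p + k + e < n && off + k + e < U.size() &&
             read[p + k + e] == U[off + k + e]) ++e;
      out.push_back({p, k + e, (int)uid, (int)off, 0});
    } else {
      while (p + k + e < n && (int)off - 1 - e >= 0 &&
             read[p + k + e] == compBase(U[off - 1 - e])) ++e;
      out.push_back({p, k + e, (int)uid, (int)off - e, 1});
    }
    p = p + e + 1;  // resume one past the last anchored k-mer start
  }
}

// [[Rcpp::export]]
List cpp_collect_unimems(std::string read, List idx) {
  UnitigSet us;
  usFromR(idx, us);
  std::vector<UniMem> mems;
  collectUniMems(read, us, mems);
  int n = (int)mems.size();
  IntegerVector rs(n), len(n), uid(n), ust(n), ori(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = mems[i].readStart; len[i] = mems[i].len;
    uid[i] = mems[i].uid + 1; ust[i] = mems[i].ustart; ori[i] = mems[i].orient;
  }
  return List::create(_["read_start"] = rs, _["length"] = len,
                      _["unitig_id"] = uid, _["unitig_offset"] = ust,
                      _["orientation"] = ori);
}

// ---------------------------------------------------------------------------
// phase 2: projection to reference anchors, collation by (ref, orientation)
// ---------------------------------------------------------------------------

struct Anchor { int rs, ref_start, len; };

// key = ref * 2 + orient
typedef std::unordered_map<int64_t, std::vector<Anchor>> AnchorGroups;

static void projectCollate(const std::vector<UniMem>& mems, const UnitigSet& us,
                           int readLen, AnchorGroups& groups) {
  groups.clear();
  for (const auto& m : mems) {
    int ulen = (int)us.unitigs[m.uid].size();
    for (int j = us.occPtr[m.uid]; j < us.occPtr[m.uid + 1]; ++j) {
      int ref = us.occRef[j], pos = us.occPos[j], ostr = us.occStrand[j];
      int aOri = m.orient ^ ostr;
      int refStart = (ostr == 0) ? pos + m.ustart
                                 : pos + (ulen - m.ustart - m.len);
      int rs = (aOri == 0) ? m.readStart : readLen - (m.readStart + m.len);
      groups[(int64_t)ref * 2 + aOri].push_back({rs, refStart, m.len});
    }
  }
}

// [[Rcpp::export]]
List cpp_project_collate(IntegerVector read_start, IntegerVector length,
                         IntegerVector unitig_id, IntegerVector unitig_offset,
                         IntegerVector orientation, int read_len, List idx) {
  UnitigSet us;
  usFromR(idx, us);
  std::vector<UniMem> mems(read_start.size());
  for (int i = 0; i < read_start.size(); ++i)
    mems[i] = {read_start[i], length[i], unitig_id[i] - 1, unitig_offset[i],
               orientation[i]};
  AnchorGroups groups;
  projectCollate(mems, us, read_len, groups);
  std::vector<int64_t> keys;
  for (auto& kv : groups) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int tot = 0;
  for (auto& kv : groups) tot += (int)kv.second.size();
  IntegerVector ref(tot), ori(tot), rs(tot), rfs(tot), len(tot);
  int o = 0;
  for (int64_t key : keys) {
    auto& v = groups[key];
    std::sort(v.begin(), v.end(), [](const Anchor& a, const Anchor& b) {
      return a.rs != b.rs ? a.rs < b.rs : a.ref_start < b.ref_start;
    });
    for (auto& a : v) {
      ref[o] = (int)(key / 2) + 1; ori[o] = (int)(key % 2);
      rs[o] = a.rs; rfs[o] = a.ref_start; len[o] = a.len; ++o;
    }
  }
  return List::create(_["ref"] = ref, _["orientation"] = ori,
                      _["read_start"] = rs, _["ref_start"] = rfs,
                      _["length"] = len);
}

// ---------------------------------------------------------------------------
// phase 3: compaction + chaining
// ---------------------------------------------------------------------------

static void compactAnchors(std::vector<Anchor>& v) {
  std::sort(v.begin(), v.end(), [](const Anchor& a, const Anchor& b) {
    return a.rs != b.rs ? a.rs < b.rs : a.ref_start < b.ref_start;
  });
  std::vector<Anchor> out;
  for (const auto& a : v) {
    bool merged = false;
    for (auto& m : out) {
      if (m.rs + m.len == a.rs && m.ref_start + m.len == a.ref_start) {
        m.len += a.len;
        merged = true;
        break;
      }
    }
    if (!merged) out.push_back(a);
  }
  v.swap(out);
}

// [[Rcpp::export]]
List cpp_compact_anchors(IntegerVector read_start, IntegerVector ref_start,
                         IntegerVector length) {
  std::vector<Anchor> v(read_start.size());
  for (int i = 0; i < read_start.size(); ++i)
    v[i] = {read_start[i], ref_start[i], length[i]};
  compactAnchors(v);
  int n = (int)v.size();
  IntegerVector rs(n), rfs(n), len(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = v[i].rs; rfs[i] = v[i].ref_start; len[i] = v[i].len;
  }
  return List::create(_["read_start"] = rs, _["ref_start"] = rfs,
                      _["length"] = len);
}

struct ChainParamsC {
  double gapLin = 0.23, gapLog = 0.5;
  int maxGap = 1000, maxChains = 200;
};

static inline double transitionCost(const Anchor& pj, const Anchor& pi,
                                    const ChainParamsC& cp, bool& admissible) {
  admissible = false;
  if (pi.rs <= pj.rs || pi.ref_start <= pj.ref_start) return 0.0;
  int dr = pi.rs - (pj.rs + pj.len);
  int dg = pi.ref_start - (pj.ref_start + pj.len);
  if (dr > cp.maxGap || dg > cp.maxGap) return 0.0;
  admissible = true;
  int d = std::abs(dr - dg);
  double cost = 0.0;
  if (d > 0) cost += cp.gapLin * d + cp.gapLog * std::log2((double)d + 1.0);
  // overlapping spans: double-counted bases are penalized once
  int ov = std::max(0, std::max(-dr, -dg));
  cost += ov;
  return cost;
}

struct ChainResult {
  double score = 0.0;
  std::vector<std::vector<int>> chains;  // anchor indices into the sorted order
};

static void chainAnchorsDP(std::vector<Anchor>& v, const ChainParamsC& cp,
                           ChainResult& res) {
  res.score = 0.0;
  res.chains.clear();
  int n = (int)v.size();
  if (n == 0) return;
  std::sort(v.begin(), v.end(), [](const Anchor& a, const Anchor& b) {
    return a.ref_start != b.ref_start ? a.ref_start < b.ref_start
                                      : a.rs < b.rs;
  });
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i) {
    double best = 0.0;
    for (int j = 0; j < i; ++j) {
      bool adm;
      double cost = transitionCost(v[j], v[i], cp, adm);
      if (adm) best = std::max(best, f[j] - cost);
    }
    f[i] = v[i].len + std::max(0.0, best);
  }
  double S = *std::max_element(f.begin(), f.end());
  res.score = S;
  const double eps = 1e-9;
  // enumerate all co-optimal chains by DFS over optimal predecessors
  std::vector<int> path;
  std::function<void(int)> dfs = [&](int i) {
    if ((int)res.chains.size() >= cp.maxChains) return;
    path.push_back(i);
    double need = f[i] - v[i].len;  // score the prefix must supply
    bool canStart = need <= eps;
    std::vector<int> preds;
    for (int j = 0; j < i; ++j) {
      bool adm;
      double cost = transitionCost(v[j], v[i], cp, adm);
      if (adm && std::fabs((f[j] - cost) - need) <= eps && f[j] - cost > eps)
        preds.push_back(j);
    }
    // smaller ref_start first (sorted order is already by ref_start)
    if (canStart) {
      std::vector<int> chain(path.rbegin(), path.rend());
      res.chains.push_back(chain);
    }
    for (int j : preds) dfs(j);
    path.pop_back();
  };
  for (int i = 0; i < n; ++i)
    if (std::fabs(f[i] - S) <= eps) dfs(i);
}

// [[Rcpp::export]]
List cpp_chain_anchors(IntegerVector read_start, IntegerVector ref_start,
                       IntegerVector length, double gap_linear,
                       double gap_log, int max_gap, int max_chains) {
  std::vector<Anchor> v(read_start.size());
  for (int i = 0; i < read_start.size(); ++i)
    v[i] = {read_start[i], ref_start[i], length[i]};
  ChainParamsC cp{gap_linear, gap_log, max_gap, max_chains};
  ChainResult res;
  chainAnchorsDP(v, cp, res);
  int n = (int)v.size();
  IntegerVector rs(n), rfs(n), len(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = v[i].rs; rfs[i] = v[i].ref_start; len[i] = v[i].len;
  }
  List chains(res.chains.size());
  for (size_t c = 0; c < res.chains.size(); ++c) {
    IntegerVector ch(res.chains[c].size());
    for (size_t j = 0; j < res.chains[c].size(); ++j) ch[j] = res.chains[c][j] + 1;
    chains[c] = ch;
  }
  return List::create(_["score"] = res.score, _["chains"] = chains,
                      _["read_start"] = rs, _["ref_start"] = rfs,
                      _["length"] = len);
}

// ---------------------------------------------------------------------------
// phase 5: score-only extension alignment (affine gaps, banded)
// ---------------------------------------------------------------------------

struct AlignParamsC {
  double match = 2.0, mismatch = -4.0, gapOpen = 5.0, gapExt = 3.0;
  int bandPad = 8;
};

static const double NEG_INF = -1e18;

// Affine-gap DP of a (read segment) vs b (reference segment).
// freeRefStart: leading unaligned reference bases cost 0 (alignment may begin
//   anywhere in b, but must end at the end of b).
// freeRefEnd: trailing unaligned reference bases cost 0 (alignment must begin
//   at the start of b, may end anywhere).
// The read segment is always aligned globally. Full (unbanded) DP: segments
// handed to this routine are short by construction (inter-anchor gaps and read
// flanks), so banding is unnecessary for exactness or speed.
static double affineSegment(const std::string& a, const std::string& b,
                            const AlignParamsC& p, bool freeRefStart,
                            bool freeRefEnd) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0) return 0.0;
  if (n == 0) return (freeRefStart || freeRefEnd) ? 0.0 : -(p.gapOpen + p.gapExt * m);
  if (m == 0) return -(p.gapOpen + p.gapExt * n);
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);  // X: gap in b (read ins), Y: gap in a
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = freeRefStart ? 0.0 : -(p.gapOpen + p.gapExt * j);
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF;
    X[0] = -(p.gapOpen + p.gapExt * i);
    Y[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double sub = (a[i - 1] == b[j - 1] && base2bits(a[i - 1]) >= 0)
                       ? p.match : p.mismatch;
      double diag = std::max({Mp[j - 1], Xp[j - 1], Yp[j - 1]});
      M[j] = (diag <= NEG_INF / 2) ? NEG_INF : diag + sub;
      double up = std::max(Mp[j] - p.gapOpen - p.gapExt, Xp[j] - p.gapExt);
      X[j] = (up <= NEG_INF / 2) ? NEG_INF : up;
      double left = std::max(M[j - 1] - p.gapOpen - p.gapExt, Y[j - 1] - p.gapExt);
      Y[j] = (left <= NEG_INF / 2) ? NEG_INF : left;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  if (!freeRefEnd) return std::max({Mp[m], Xp[m], Yp[m]});
  double best = NEG_INF;
  for (int j = 0; j <= m; ++j)
    best = std::max(best, std::max(Mp[j], std::max(Xp[j], Yp[j])));
  return best;
}

// extension score of one read end along a chain of exact-match anchors
static double extensionScore(const std::string& read, const std::string& ref,
                             std::vector<Anchor> chain, const AlignParamsC& p,
                             int* dpCounter = nullptr) {
  std::sort(chain.begin(), chain.end(), [](const Anchor& a, const Anchor& b) {
    return a.rs < b.rs;
  });
  // trim anchor overlaps (possible inside a chain; exactness preserved since
  // trimming an exact match start keeps it exact)
  int prevRe = -1, prevGe = -1;
  double score = 0.0;
  std::vector<Anchor> cl;
  for (auto a : chain) {
    if (prevRe >= 0) {
      int o = std::max(prevRe - a.rs, prevGe - a.ref_start);
      if (o > 0) { a.rs += o; a.ref_start += o; a.len -= o; }
      if (a.len <= 0) continue;
    }
    prevRe = a.rs + a.len;
    prevGe = a.ref_start + a.len;
    cl.push_back(a);
  }
  if (cl.empty()) return NEG_INF;
  for (const auto& a : cl) score += p.match * a.len;
  if (dpCounter) ++(*dpCounter);
  // prefix (free leading reference bases within the window)
  const Anchor& a0 = cl.front();
  if (a0.rs > 0) {
    int plen = a0.rs;
    int refEnd = a0.ref_start;
    int refBeg = std::max(0, refEnd - (plen + p.bandPad));
    score += affineSegment(read.substr(0, plen),
                           ref.substr(refBeg, refEnd - refBeg), p, true, false);
  }
  // inter-anchor gaps (global)
  for (size_t i = 1; i < cl.size(); ++i) {
    int rb = cl[i - 1].rs + cl[i - 1].len, re = cl[i].rs;
    int gb = cl[i - 1].ref_start + cl[i - 1].len, ge = cl[i].ref_start;
    if (re > rb || ge > gb)
      score += affineSegment(read.substr(rb, re - rb), ref.substr(gb, ge - gb),
                             p, false, false);
  }
  // suffix (free trailing reference bases within the window)
  const Anchor& aL = cl.back();
  int rtail = (int)read.size() - (aL.rs + aL.len);
  if (rtail > 0) {
    int refBeg = aL.ref_start + aL.len;
    int refEnd = std::min((int)ref.size(), refBeg + rtail + p.bandPad);
    if (refBeg > (int)ref.size()) refBeg = (int)ref.size();
    score += affineSegment(read.substr(aL.rs + aL.len, rtail),
                           ref.substr(refBeg, refEnd - refBeg), p, false, true);
  }
  return score;
}

// [[Rcpp::export]]
double cpp_extension_score(std::string read, std::string ref,
                           IntegerVector read_start, IntegerVector ref_start,
                           IntegerVector length, double match, double mismatch,
                           double gap_open, double gap_ext, int band_pad) {
  std::vector<Anchor> chain(read_start.size());
  for (int i = 0; i < read_start.size(); ++i) {
    if (ref_start[i] < 0 || ref_start[i] + length[i] > (int)ref.size())
      stop("chain anchor outside reference bounds");
    chain[i] = {read_start[i], ref_start[i], length[i]};
  }
  AlignParamsC p{match, mismatch, gap_open, gap_ext, band_pad};
  return extensionScore(read, ref, chain, p);
}

// ---------------------------------------------------------------------------
// phase 4: paired-end merging
// ---------------------------------------------------------------------------

struct ChainSummary {
  int ref;       // 0-based ordinal
  int orient;    // 0 FW, 1 RC (of the read end)
  double score;
  int wlo, whi;  // predicted reference window of the full read end
  std::vector<Anchor> anchors;  // coordinates on the oriented read
};

struct Candidate {
  int ref;
  int c1, c2;      // chain indices per end (-1 if absent / orphan)
  bool dovetail;
  double pairChainScore;
  int fragStart, fragEnd;
};

static void mergePairsC(const std::vector<ChainSummary>& ch1,
                        const std::vector<ChainSummary>& ch2,
                        int maxFragLen, bool allowDovetail,
                        std::vector<Candidate>& out) {
  out.clear();
  for (size_t i = 0; i < ch1.size(); ++i) {
    for (size_t j = 0; j < ch2.size(); ++j) {
      if (ch1[i].ref != ch2[j].ref) continue;
      if (ch1[i].orient == ch2[j].orient) continue;
      const ChainSummary& fw = (ch1[i].orient == 0) ? ch1[i] : ch2[j];
      const ChainSummary& rc = (ch1[i].orient == 0) ? ch2[j] : ch1[i];
      bool dove = rc.wlo < fw.wlo;
      if (dove && !allowDovetail) continue;
      int lo = std::min(ch1[i].wlo, ch2[j].wlo);
      int hi = std::max(ch1[i].whi, ch2[j].whi);
      if (hi - lo > maxFragLen) continue;
      out.push_back({ch1[i].ref, (int)i, (int)j, dove,
                     ch1[i].score + ch2[j].score, lo, hi});
    }
  }
  std::sort(out.begin(), out.end(), [](const Candidate& a, const Candidate& b) {
    if (a.dovetail != b.dovetail) return !a.dovetail;
    if (a.pairChainScore != b.pairChainScore) return a.pairChainScore > b.pairChainScore;
    if (a.ref != b.ref) return a.ref < b.ref;
    return a.fragStart < b.fragStart;
  });
}

// [[Rcpp::export]]
List cpp_merge_pairs(IntegerVector ref1, IntegerVector ori1, NumericVector sc1,
                     IntegerVector lo1, IntegerVector hi1,
                     IntegerVector ref2, IntegerVector ori2, NumericVector sc2,
                     IntegerVector lo2, IntegerVector hi2,
                     int max_fragment_len, bool allow_dovetails) {
  std::vector<ChainSummary> c1(ref1.size()), c2(ref2.size());
  for (int i = 0; i < ref1.size(); ++i)
    c1[i] = {ref1[i] - 1, ori1[i], sc1[i], lo1[i], hi1[i], {}};
  for (int i = 0; i < ref2.size(); ++i)
    c2[i] = {ref2[i] - 1, ori2[i], sc2[i], lo2[i], hi2[i], {}};
  std::vector<Candidate> cand;
  mergePairsC(c1, c2, max_fragment_len, allow_dovetails, cand);
  int n = (int)cand.size();
  IntegerVector ref(n), i1(n), i2(n), fs(n), fe(n);
  LogicalVector dv(n);
  NumericVector ps(n);
  for (int i = 0; i < n; ++i) {
    ref[i] = cand[i].ref + 1; i1[i] = cand[i].c1 + 1; i2[i] = cand[i].c2 + 1;
    dv[i] = cand[i].dovetail; ps[i] = cand[i].pairChainScore;
    fs[i] = cand[i].fragStart; fe[i] = cand[i].fragEnd;
  }
  return List::create(_["ref"] = ref, _["chain1"] = i1, _["chain2"] = i2,
                      _["dovetail"] = dv, _["pair_chain_score"] = ps,
                      _["fragment_start"] = fs, _["fragment_end"] = fe);
}

// ---------------------------------------------------------------------------
// batch runner: phases 1-5 + decoy classification per fragment
// ---------------------------------------------------------------------------

struct RunParamsC {
  ChainParamsC chain;
  AlignParamsC aln;
  double tauPre = 0.65; bool preFilter = false;
  double tauPost = 0.65; bool postFilter = true;
  int maxFragLen = 1000;
  bool allowOrphans = false, allowDovetails = false;
  double minScoreFraction = 0.65;
  bool useCache = true;
};

// phases 1-3 for one read end; returns chain summaries (oriented-read coords)
static void mapReadEnd(const std::string& read, const std::string& readRC,
                       const UnitigSet& us,
                       const std::vector<std::string>& refs,
                       const RunParamsC& rp,
                       std::vector<ChainSummary>& out) {
  out.clear();
  int n = (int)read.size();
  if (n < us.k) return;
  std::vector<UniMem> mems;
  collectUniMems(read, us, mems);
  if (mems.empty()) return;
  AnchorGroups groups;
  projectCollate(mems, us, n, groups);
  // optional pre-chaining filter on total anchor bases per group
  if (rp.preFilter) {
    double M = 0;
    for (auto& kv : groups) {
      double tot = 0;
      for (auto& a : kv.second) tot += a.len;
      M = std::max(M, tot);
    }
    for (auto it = groups.begin(); it != groups.end();) {
      double tot = 0;
      for (auto& a : it->second) tot += a.len;
      if (tot < rp.tauPre * M) it = groups.erase(it);
      else ++it;
    }
  }
  std::vector<int64_t> keys;
  for (auto& kv : groups) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  double S = 0.0;
  std::vector<ChainSummary> all;
  for (int64_t key : keys) {
    auto& v = groups[key];
    compactAnchors(v);
    ChainResult cr;
    chainAnchorsDP(v, rp.chain, cr);
    int ref = (int)(key / 2), ori = (int)(key % 2);
    int reflen = (int)refs[ref].size();
    for (auto& ch : cr.chains) {
      ChainSummary cs;
      cs.ref = ref; cs.orient = ori; cs.score = cr.score;
      cs.anchors.reserve(ch.size());
      for (int ix : ch) cs.anchors.push_back(v[ix]);
      const Anchor& a0 = cs.anchors.front();
      const Anchor& aL = cs.anchors.back();
      int lo = a0.ref_start - a0.rs;
      int hi = aL.ref_start + aL.len + (n - (aL.rs + aL.len));
      cs.wlo = std::max(0, lo);
      cs.whi = std::min(reflen, hi);
      all.push_back(std::move(cs));
    }
    S = std::max(S, cr.score);
  }
  for (auto& cs : all)
    if (!rp.postFilter || cs.score >= rp.tauPost * S) out.push_back(cs);
  (void)readRC;
}

struct ScoreCache {
  std::unordered_map<std::string, double> map;
  int hits = 0;
};

static double scoreCandidateEnd(const std::string& readOri,
                                const std::string& ref,
                                const ChainSummary& cs,
                                const RunParamsC& rp, ScoreCache* cache,
                                int endId, int& dpCount) {
  std::string key;
  if (cache) {
    // key: end id, orientation, reference window, relative anchor layout
    key.reserve(64 + (cs.whi - cs.wlo));
    key += (char)('0' + endId);
    key += (char)('0' + cs.orient);
    key.append(ref, cs.wlo, cs.whi - cs.wlo);
    for (const auto& a : cs.anchors) {
      key += ';';
      key += std::to_string(a.rs); key += ',';
      key += std::to_string(a.ref_start - cs.wlo); key += ',';
      key += std::to_string(a.len);
    }
    auto it = cache->map.find(key);
    if (it != cache->map.end()) { ++cache->hits; return it->second; }
  }
  double s = extensionScore(readOri, ref, cs.anchors, rp.aln, &dpCount);
  if (cache) cache->map.emplace(std::move(key), s);
  return s;
}

// [[Rcpp::export]]
List cpp_run_fragments(CharacterVector reads1, CharacterVector reads2,
                       List idx, CharacterVector refSeqs, LogicalVector isDecoy,
                       List params) {
  UnitigSet us;
  usFromR(idx, us);
  std::vector<std::string> refs(refSeqs.size());
  for (R_xlen_t i = 0; i < refSeqs.size(); ++i) refs[i] = as<std::string>(refSeqs[i]);

  RunParamsC rp;
  rp.chain.gapLin = as<double>(params["gap_linear_coeff"]);
  rp.chain.gapLog = as<double>(params["gap_log_coeff"]);
  rp.chain.maxGap = as<int>(params["max_anchor_gap"]);
  rp.chain.maxChains = as<int>(params["max_chains"]);
  rp.aln.match = as<double>(params["match"]);
  rp.aln.mismatch = as<double>(params["mismatch"]);
  rp.aln.gapOpen = as<double>(params["gap_open"]);
  rp.aln.gapExt = as<double>(params["gap_extend"]);
  rp.aln.bandPad = as<int>(params["band_pad"]);
  rp.tauPre = as<double>(params["tau_pre"]);
  rp.preFilter = as<bool>(params["pre_filter_enabled"]);
  rp.tauPost = as<double>(params["tau_post"]);
  rp.postFilter = as<bool>(params["post_filter_enabled"]);
  rp.maxFragLen = as<int>(params["max_fragment_len"]);
  rp.allowOrphans = as<bool>(params["allow_orphans"]);
  rp.allowDovetails = as<bool>(params["allow_dovetails"]);
  rp.minScoreFraction = as<double>(params["min_score_fraction"]);
  rp.useCache = as<bool>(params["use_cache"]);

  bool paired = reads2.size() > 0;
  int nf = (int)reads1.size();

  IntegerVector status(nf);  // 0 ALIGNED, 1 DECOY, 2 UNALIGNED
  NumericVector bestTx(nf), bestDecoy(nf);
  // best decoy mapping per fragment (for SAM emission of decoy records)
  IntegerVector decRef(nf, NA_INTEGER), decPos1(nf, NA_INTEGER),
      decPos2(nf, NA_INTEGER), decOri1(nf, NA_INTEGER);
  int dpCount = 0, cacheHits = 0;

  // flattened survivor table
  std::vector<int> svFrag, svRef, svPos1, svPos2, svOri1, svDove;
  std::vector<double> svScore, svScore1, svScore2;

  std::vector<ChainSummary> ch1, ch2;
  for (int f = 0; f < nf; ++f) {
    std::string r1 = as<std::string>(reads1[f]);
    std::string r1rc = revcompStr(r1);
    mapReadEnd(r1, r1rc, us, refs, rp, ch1);
    std::string r2, r2rc;
    if (paired) {
      r2 = as<std::string>(reads2[f]);
      r2rc = revcompStr(r2);
      mapReadEnd(r2, r2rc, us, refs, rp, ch2);
    }

    std::vector<Candidate> cand;
    if (paired) {
      if (!ch1.empty() && !ch2.empty()) {
        mergePairsC(ch1, ch2, rp.maxFragLen, rp.allowDovetails, cand);
      }
      if (cand.empty() && rp.allowOrphans) {
        for (size_t i = 0; i < ch1.size(); ++i)
          cand.push_back({ch1[i].ref, (int)i, -1, false, ch1[i].score,
                          ch1[i].wlo, ch1[i].whi});
        for (size_t j = 0; j < ch2.size(); ++j)
          cand.push_back({ch2[j].ref, -1, (int)j, false, ch2[j].score,
                          ch2[j].wlo, ch2[j].whi});
      }
    } else {
      for (size_t i = 0; i < ch1.size(); ++i)
        cand.push_back({ch1[i].ref, (int)i, -1, false, ch1[i].score,
                        ch1[i].wlo, ch1[i].whi});
    }

    double maxObtainable = rp.aln.match * (double)(r1.size() + r2.size());
    double threshold = rp.minScoreFraction * maxObtainable;

    ScoreCache cache;
    ScoreCache* cptr = rp.useCache ? &cache : nullptr;
    double bTx = R_NegInf, bDecoy = R_NegInf;
    struct Scored { int ref, pos1, pos2, ori1; bool dove; double s, s1, s2; };
    std::vector<Scored> scored;
    bool anyNonDove = false;
    for (auto& c : cand) if (!c.dovetail) anyNonDove = true;
    for (auto& c : cand) {
      // dovetails enter scoring only when no non-dovetail candidate exists
      if (c.dovetail && anyNonDove) continue;
      double s1 = 0.0, s2 = 0.0;
      int p1 = NA_INTEGER, p2 = NA_INTEGER, o1 = NA_INTEGER;
      if (c.c1 >= 0) {
        const ChainSummary& cs = ch1[c.c1];
        const std::string& ro = (cs.orient == 0) ? r1 : r1rc;
        s1 = scoreCandidateEnd(ro, refs[c.ref], cs, rp, cptr, 1, dpCount);
        p1 = cs.wlo; o1 = cs.orient;
      }
      if (c.c2 >= 0) {
        const ChainSummary& cs = ch2[c.c2];
        const std::string& ro = (cs.orient == 0) ? r2 : r2rc;
        s2 = scoreCandidateEnd(ro, refs[c.ref], cs, rp, cptr, 2, dpCount);
        p2 = cs.wlo;
      }
      double s = s1 + s2;
      if (isDecoy[c.ref]) {
        if (s > bDecoy) {
          bDecoy = s;
          decRef[f] = c.ref + 1; decPos1[f] = p1; decPos2[f] = p2;
          decOri1[f] = o1;
        }
      } else bTx = std::max(bTx, s);
      scored.push_back({c.ref, p1, p2, o1, (bool)c.dovetail, s, s1, s2});
    }
    cacheHits += cache.hits;

    bestTx[f] = (bTx > NEG_INF / 2) ? bTx : NA_REAL;
    bestDecoy[f] = (bDecoy > NEG_INF / 2) ? bDecoy : NA_REAL;
    if (scored.empty()) { status[f] = 2; continue; }
    if (bDecoy > bTx) { status[f] = 1; continue; }
    // keep non-decoy mappings at/above the minimum valid alignment score
    bool any = false;
    for (auto& s : scored) {
      if (isDecoy[s.ref]) continue;
      if (s.s < threshold) continue;
      any = true;
      svFrag.push_back(f + 1); svRef.push_back(s.ref + 1);
      svPos1.push_back(s.pos1); svPos2.push_back(s.pos2);
      svOri1.push_back(s.ori1); svDove.push_back(s.dove ? 1 : 0);
      svScore.push_back(s.s); svScore1.push_back(s.s1); svScore2.push_back(s.s2);
    }
    status[f] = any ? 0 : 2;
  }

  return List::create(
    _["status"] = status, _["best_txome_score"] = bestTx,
    _["best_decoy_score"] = bestDecoy,
    _["mappings"] = List::create(
      _["fragment"] = wrap(svFrag), _["ref"] = wrap(svRef),
      _["pos1"] = wrap(svPos1), _["pos2"] = wrap(svPos2),
      _["orientation1"] = wrap(svOri1), _["dovetail"] = wrap(svDove),
      _["score"] = wrap(svScore), _["score1"] = wrap(svScore1),
      _["score2"] = wrap(svScore2)),
    _["decoy_ref"] = decRef, _["decoy_pos1"] = decPos1,
    _["decoy_pos2"] = decPos2, _["decoy_orientation1"] = decOri1,
    _["alignments_computed"] = dpCount, _["cache_hits"] = cacheHits);
}

// chains of a single read end (exposed for the R-level mapping API)
// [[Rcpp::export]]
List cpp_map_read_end(std::string read, List idx, CharacterVector refSeqs,
                      List params) {
  UnitigSet us;
  usFromR(idx, us);
  std::vector<std::string> refs(refSeqs.size());
  for (R_xlen_t i = 0; i < refSeqs.size(); ++i) refs[i] = as<std::string>(refSeqs[i]);
  RunParamsC rp;
  rp.chain.gapLin = as<double>(params["gap_linear_coeff"]);
  rp.chain.gapLog = as<double>(params["gap_log_coeff"]);
  rp.chain.maxGap = as<int>(params["max_anchor_gap"]);
  rp.chain.maxChains = as<int>(params["max_chains"]);
  rp.tauPre = as<double>(params["tau_pre"]);
  rp.preFilter = as<bool>(params["pre_filter_enabled"]);
  rp.tauPost = as<double>(params["tau_post"]);
  rp.postFilter = as<bool>(params["post_filter_enabled"]);
  std::string rc = revcompStr(read);
  std::vector<ChainSummary> chains;
  mapReadEnd(read, rc, us, refs, rp, chains);
  int n = (int)chains.size();
  IntegerVector ref(n), ori(n), lo(n), hi(n);
  NumericVector sc(n);
  List anchors(n);
  for (int i = 0; i < n; ++i) {
    ref[i] = chains[i].ref + 1; ori[i] = chains[i].orient;
    lo[i] = chains[i].wlo; hi[i] = chains[i].whi; sc[i] = chains[i].score;
    int na = (int)chains[i].anchors.size();
    IntegerVector ars(na), agf(na), alen(na);
    for (int j = 0; j < na; ++j) {
      ars[j] = chains[i].anchors[j].rs;
      agf[j] = chains[i].anchors[j].ref_start;
      alen[j] = chains[i].anchors[j].len;
    }
    anchors[i] = List::create(_["read_start"] = ars, _["ref_start"] = agf,
                              _["length"] = alen);
  }
  return List::create(_["ref"] = ref, _["orientation"] = ori, _["score"] = sc,
                      _["window_lo"] = lo, _["window_hi"] = hi,
                      _["anchors"] = anchors);
}

// ---------------------------------------------------------------------------
// minimizers (decoy segment mapping support)
// ---------------------------------------------------------------------------

static inline uint64_t mixHash(uint64_t x) {
  x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}

// (w,k)-minimizers of a sequence; positions 0-based; k-mers containing non-ACGT
// are skipped. Returns hash values (as doubles, 2^53-safe) and positions.
// [[Rcpp::export]]
List cpp_minimizers(std::string seq, int k, int w) {
  int n = (int)seq.size();
  std::vector<double> hs;
  std::vector<int> ps;
  if (n >= k) {
    std::vector<uint64_t> H(n - k + 1, UINT64_MAX);
    for (int i = 0; i + k <= n; ++i) {
      uint64_t fwd, rc;
      if (!encodeKmer(seq, i, k, fwd, rc)) continue;
      H[i] = mixHash(std::min(fwd, rc)) >> 12;  // keep 52 bits
    }
    int lastPos = -1;
    for (int i = 0; i + k + w - 1 <= n; ++i) {
      uint64_t best = UINT64_MAX; int bp = -1;
      for (int j = i; j < i + w; ++j)
        if (H[j] < best) { best = H[j]; bp = j; }
      if (bp >= 0 && bp != lastPos) {
        hs.push_back((double)best);
        ps.push_back(bp);
        lastPos = bp;
      }
    }
  }
  return List::create(_["hash"] = wrap(hs), _["pos"] = wrap(ps));
}
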