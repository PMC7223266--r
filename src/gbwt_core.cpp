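// Core engine for the Graph BWT: a run-length encoded, record-partitioned
// FM-index of oriented-node paths. Node values are integers: 0 is the
// end-marker, a forward node with graph id n encodes to 2n, its reverse to
// 2n+1. The BWT is partitioned into one record per node; each record body
// stores the successor sequence of the occurrences of that node, sorted by
// reverse-prefix key (ties broken by path id via distinct end-markers).
//
// The dynamic form (Dyn) supports incremental path insertion; the flat form
// (an R list of integer vectors) is the canonical, serializable index used
// by the query functions.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

struct Dyn {
  // indexed by node value; runs[v] = run-length encoded successor sequence
  std::vector<std::vector<std::pair<int, int> > > runs;
  std::vector<std::map<int, long long> > cnt;  // per node: successor -> count
  std::vector<long long> blen;                 // body length per node

  void ensure(int v) {
    if ((int)runs.size() <= v) {
      runs.resize(v + 1);
      cnt.resize(v + 1);
      blen.resize(v + 1, 0);
    }
  }

  // occurrences of w in bodies of records v' < v (BWT.rank(v, w))
  long long num_before(int v, int w) const {
    long long s = 0;
    int lim = std::min<int>(v, (int)runs.size());
    for (int u = 0; u < lim; u++) {
      std::map<int, long long>::const_iterator it = cnt[u].find(w);
      if (it != cnt[u].end()) s += it->second;
    }
    return s;
  }

  // occurrences of w among the first i body symbols of record v
  long long rank_in_body(int v, long long i, int w) const {
    if (v >= (int)runs.size()) return 0;
    long long pos = 0, r = 0;
    for (size_t k = 0; k < runs[v].size(); k++) {
      if (pos >= i) break;
      long long take = std::min<long long>(runs[v][k].second, i - pos);
      if (runs[v][k].first == w) r += take;
      pos += runs[v][k].second;
    }
    return r;
  }

  int body_at(int v, long long i) const {
    if (v < 0 || v >= (int)runs.size()) return -1;
    long long pos = 0;
    for (size_t k = 0; k < runs[v].size(); k++) {
      if (i < pos + runs[v][k].second) return runs[v][k].first;
      pos += runs[v][k].second;
    }
    return -1;
  }

  long long lf_off(int v, long long i, int w) const {
    return num_before(v, w) + rank_in_body(v, i, w);
  }

  // insert successor symbol w at offset p of record v, keeping runs maximal
  void insert_at(int v, long long p, int w) {
    ensure(v);
    if (w > 0) ensure(w);
    std::vector<std::pair<int, int> > &rs = runs[v];
    long long pos = 0;
    size_t k = 0;
    for (; k < rs.size(); k++) {
      if (p <= pos + rs[k].second) break;
      pos += rs[k].second;
    }
    if (k == rs.size()) {  // append at the very end
      if (!rs.empty() && rs.back().first == w)
        rs.back().second++;
      else
        rs.push_back(std::make_pair(w, 1));
    } else if (p == pos) {  // boundary before run k
      if (k > 0 && rs[k - 1].first == w)
        rs[k - 1].second++;
      else if (rs[k].first == w)
        rs[k].second++;
      else
        rs.insert(rs.begin() + k, std::make_pair(w, 1));
    } else if (p == pos + rs[k].second) {  // boundary after run k
      if (rs[k].first == w)
        rs[k].second++;
      else if (k + 1 < rs.size() && rs[k + 1].first == w)
        rs[k + 1].second++;
      else
        rs.insert(rs.begin() + k + 1, std::make_pair(w, 1));
    } else {  // strictly inside run k
      if (rs[k].first == w) {
        rs[k].second++;
      } else {
        int c = rs[k].first;
        long long left = p - pos, right = rs[k].second - left;
        rs[k].second = (int)left;
        rs.insert(rs.begin() + k + 1, std::make_pair(w, 1));
        rs.insert(rs.begin() + k + 2, std::make_pair(c, (int)right));
      }
    }
    cnt[v][w]++;
    blen[v]++;
  }

  // Insert one path (front to back). The new path gets the largest id, so
  // its end-marker appends at the end of record 0 and each subsequent
  // insertion offset is the LF-image of the previous one computed against
  // the current (partially updated) index.
  void insert_path(const std::vector<int> &path) {
    ensure(0);
    long long j = blen[0];
    insert_at(0, j, path[0]);
    long long p = rank_in_body(0, j, path[0]);
    for (size_t k = 0; k < path.size(); k++) {
      int v = path[k];
      int w = (k + 1 < path.size()) ? path[k + 1] : 0;
      insert_at(v, p, w);
      if (w == 0) break;
      p = num_before(v, w) + rank_in_body(v, p, w);
    }
  }
};

// flatten a dynamic index: headers (sorted local alphabets with cumulative
// ranks), concatenated run arrays, and the sample table built by walking
// every path and sampling on-path offsets = 0 (mod d) plus final positions.
static List core_from_dyn(const Dyn &D, int d) {
  std::vector<int> nodes;
  for (int v = 0; v < (int)D.runs.size(); v++)
    if (D.blen[v] > 0) nodes.push_back(v);

  std::vector<int> hptr, hsucc, hrank, rptr, rsucc, rlen, blen;
  hptr.push_back(0);
  rptr.push_back(0);
  std::map<int, long long> tot;
  for (size_t ni = 0; ni < nodes.size(); ni++) {
    int v = nodes[ni];
    for (std::map<int, long long>::const_iterator it = D.cnt[v].begin();
         it != D.cnt[v].end(); ++it) {
      if (it->second <= 0) continue;
      hsucc.push_back(it->first);
      long long t = tot.count(it->first) ? tot[it->first] : 0;
      hrank.push_back((int)t);
    }
    hptr.push_back((int)hsucc.size());
    for (std::map<int, long long>::const_iterator it = D.cnt[v].begin();
         it != D.cnt[v].end(); ++it)
      if (it->second > 0) tot[it->first] += it->second;
    for (size_t k = 0; k < D.runs[v].size(); k++) {
      rsucc.push_back(D.runs[v][k].first);
      rlen.push_back(D.runs[v][k].second);
    }
    rptr.push_back((int)rsucc.size());
    blen.push_back((int)D.blen[v]);
  }

  long long m = (D.blen.size() > 0) ? D.blen[0] : 0;
  std::map<std::pair<int, long long>, int> smp;
  for (long long j = 0; j < m; j++) {
    int v = 0;
    long long off = j, t = 0;
    while (true) {
      int w = D.body_at(v, off);
      if (w <= 0) break;
      long long noff = D.lf_off(v, off, w);
      int wn = D.body_at(w, noff);
      if (t % d == 0 || wn == 0) smp[std::make_pair(w, noff)] = (int)j;
      v = w;
      off = noff;
      t++;
      if (wn == 0) break;
    }
  }
  std::vector<int> snode, soff, sid;
  for (std::map<std::pair<int, long long>, int>::const_iterator it = smp.begin();
       it != smp.end(); ++it) {
    snode.push_back(it->first.first);
    soff.push_back((int)it->first.second);
    sid.push_back(it->second);
  }

  return List::create(
      _["nodes"] = wrap(nodes), _["hdr_ptr"] = wrap(hptr),
      _["hdr_succ"] = wrap(hsucc), _["hdr_rank"] = wrap(hrank),
      _["run_ptr"] = wrap(rptr), _["run_succ"] = wrap(rsucc),
      _["run_len"] = wrap(rlen), _["blen"] = wrap(blen),
      _["smp_node"] = wrap(snode), _["smp_off"] = wrap(soff),
      _["smp_id"] = wrap(sid), _["n_paths"] = (int)m);
}

static Dyn dyn_from_core(List core) {
  Dyn D;
  IntegerVector nodes = core["nodes"];
  if (nodes.size() == 0) return D;
  IntegerVector rptr = core["run_ptr"], rsucc = core["run_succ"],
                rlen = core["run_len"];
  int maxv = 0;
  for (int i = 0; i < nodes.size(); i++) maxv = std::max(maxv, nodes[i]);
  for (int i = 0; i < rsucc.size(); i++) maxv = std::max(maxv, rsucc[i]);
  D.ensure(maxv);
  for (int i = 0; i < nodes.size(); i++) {
    int v = nodes[i];
    for (int k = rptr[i]; k < rptr[i + 1]; k++) {
      D.runs[v].push_back(std::make_pair(rsucc[k], rlen[k]));
      D.cnt[v][rsucc[k]] += rlen[k];
      D.blen[v] += rlen[k];
    }
  }
  return D;
}

// [[Rcpp::export]]
List gbwt_insert_cpp(List core, List paths, int d) {
  Dyn D = dyn_from_core(core);
  for (int i = 0; i < paths.size(); i++) {
    IntegerVector p = paths[i];
    std::vector<int> pv(p.begin(), p.end());
    D.insert_path(pv);
  }
  return core_from_dyn(D, d);
}

// [[Rcpp::export]]
List gbwt_from_runs_cpp(IntegerVector nodes, List runsucc, List runlen, int d) {
  Dyn D;
  int maxv = 0;
  for (int i = 0; i < nodes.size(); i++) maxv = std::max(maxv, nodes[i]);
  for (int i = 0; i < runsucc.size(); i++) {
    IntegerVector s = runsucc[i];
    for (int k = 0; k < s.size(); k++) maxv = std::max(maxv, s[k]);
  }
  D.ensure(maxv);
  for (int i = 0; i < nodes.size(); i++) {
    int v = nodes[i];
    IntegerVector s = runsucc[i], l = runlen[i];
    for (int k = 0; k < s.size(); k++) {
      D.runs[v].push_back(std::make_pair(s[k], l[k]));
      D.cnt[v][s[k]] += l[k];
      D.blen[v] += l[k];
    }
  }
  return core_from_dyn(D, d);
}

// light read-only view over the flat form
struct View {
  IntegerVector nodes, hptr, hsucc, hrank, rptr, rsucc, rlen, blen;
  IntegerVector snode, soff, sid;
  std::map<int, int> idx;
  View(List core)
      : nodes(as<IntegerVector>(core["nodes"])),
        hptr(as<IntegerVector>(core["hdr_ptr"])),
        hsucc(as<IntegerVector>(core["hdr_succ"])),
        hrank(as<IntegerVector>(core["hdr_rank"])),
        rptr(as<IntegerVector>(core["run_ptr"])),
        rsucc(as<IntegerVector>(core["run_succ"])),
        rlen(as<IntegerVector>(core["run_len"])),
        blen(as<IntegerVector>(core["blen"])),
        snode(as<IntegerVector>(core["smp_node"])),
        soff(as<IntegerVector>(core["smp_off"])),
        sid(as<IntegerVector>(core["smp_id"])) {
    for (int i = 0; i < nodes.size(); i++) idx[nodes[i]] = i;
  }
  int rec(int v) const {
    std::map<int, int>::const_iterator it = idx.find(v);
    return it == idx.end() ? -1 : it->second;
  }
  long long rank_in_body(int ri, long long i, int w) const {
    long long pos = 0, r = 0;
    for (int k = rptr[ri]; k < rptr[ri + 1]; k++) {
      if (pos >= i) break;
      long long take = std::min<long long>(rlen[k], i - pos);
      if (rsucc[k] == w) r += take;
      pos += rlen[k];
    }
    return r;
  }
  long long cum_rank(int ri, int w) const {
    for (int k = hptr[ri]; k < hptr[ri + 1]; k++)
      if (hsucc[k] == w) return hrank[k];
    return -1;
  }
  int body_at(int ri, long long i) const {
    long long pos = 0;
    for (int k = rptr[ri]; k < rptr[ri + 1]; k++) {
      if (i < pos + rlen[k]) return rsucc[k];
      pos += rlen[k];
    }
    return -1;
  }
  int sample_at(int v, long long off) const {
    int lo = 0, hi = snode.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (snode[mid] < v || (snode[mid] == v && soff[mid] < off))
        lo = mid + 1;
      else
        hi = mid;
    }
    if (lo < snode.size() && snode[lo] == v && soff[lo] == off) return sid[lo];
    return -1;
  }
  long long total_size() const {
    long long s = 0;
    for (int i = 0; i < blen.size(); i++) s += blen[i];
    return s;
  }
};

// [[Rcpp::export]]
IntegerVector gbwt_lf_cpp(List core, int node, int off, int w) {
  View V(core);
  int ri = V.rec(node);
  if (ri < 0) return IntegerVector::create(-1, -1);
  long long hr = V.cum_rank(ri, w);
  if (hr < 0) return IntegerVector::create(-1, -1);
  long long r = V.rank_in_body(ri, off, w);
  return IntegerVector::create(w, (int)(hr + r));
}

// [[Rcpp::export]]
IntegerVector gbwt_extend_cpp(List core, int node, int sp, int ep, int w) {
  if (ep < sp) return IntegerVector::create(-1, 0, -1);
  View V(core);
  int ri = V.rec(node);
  if (ri < 0) return IntegerVector::create(-1, 0, -1);
  long long hr = V.cum_rank(ri, w);
  if (hr < 0) return IntegerVector::create(-1, 0, -1);
  long long nsp = hr + V.rank_in_body(ri, sp, w);
  long long nep = hr + V.rank_in_body(ri, (long long)ep + 1, w) - 1;
  if (nsp > nep) return IntegerVector::create(-1, 0, -1);
  return IntegerVector::create(w, (int)nsp, (int)nep);
}

// [[Rcpp::export]]
IntegerVector gbwt_find_cpp(List core, IntegerVector pattern) {
  View V(core);
  int ri = V.rec(pattern[0]);
  if (ri < 0) return IntegerVector::create(-1, 0, -1);
  int node = pattern[0], sp = 0, ep = V.blen[ri] - 1;
  for (int i = 1; i < pattern.size(); i++) {
    int w = pattern[i];
    int nri = V.rec(node);
    long long hr = V.cum_rank(nri, w);
    if (hr < 0) return IntegerVector::create(-1, 0, -1);
    long long nsp = hr + V.rank_in_body(nri, sp, w);
    long long nep = hr + V.rank_in_body(nri, (long long)ep + 1, w) - 1;
    if (nsp > nep) return IntegerVector::create(-1, 0, -1);
    node = w;
    sp = (int)nsp;
    ep = (int)nep;
  }
  return IntegerVector::create(node, sp, ep);
}

// [[Rcpp::export]]
IntegerVector gbwt_extract_cpp(List core, int j) {
  View V(core);
  std::vector<int> out;
  int v = 0;
  long long off = j;
  long long guard = 4 * V.total_size() + 8;
  while (true) {
    int ri = V.rec(v);
    if (ri < 0) stop("malformed index: missing record");
    int w = V.body_at(ri, off);
    if (w <= 0) break;
    out.push_back(w);
    off = V.cum_rank(ri, w) + V.rank_in_body(ri, off, w);
    v = w;
    if ((long long)out.size() > guard) stop("malformed index: extract did not terminate");
  }
  return wrap(out);
}

// [[Rcpp::export]]
int gbwt_body_at_cpp(List core, int node, int off) {
  View V(core);
  int ri = V.rec(node);
  if (ri < 0) return -1;
  return V.body_at(ri, off);
}

// [[Rcpp::export]]
IntegerVector gbwt_locate_direct_cpp(List core, int node, int sp, int ep) {
  View V(core);
  std::vector<int> out;
  long long guard = 4 * V.total_size() + 8;
  for (int i = sp; i <= ep; i++) {
    int v = node;
    long long off = i, steps = 0;
    while (true) {
      int s = V.sample_at(v, off);
      if (s >= 0) {
        out.push_back(s);
        break;
      }
      int ri = V.rec(v);
      int w = V.body_at(ri, off);
      if (w <= 0) stop("malformed index: unsampled terminal position");
      off = V.cum_rank(ri, w) + V.rank_in_body(ri, off, w);
      v = w;
      if (++steps > guard) stop("malformed index: locate did not terminate");
    }
  }
  return wrap(out);
}

// Fast locate: advance whole ranges, one LF per run, reporting sampled
// positions as they are met. Returns the multiset sorted ascending.
// [[Rcpp::export]]
IntegerVector gbwt_locate_fast_cpp(List core, int node, int sp, int ep) {
  View V(core);
  std::vector<int> out;
  struct Rng {
    int v, lo, hi;
  };
  std::vector<Rng> work;
  if (sp <= ep) {
    Rng r;
    r.v = node;
    r.lo = sp;
    r.hi = ep;
    work.push_back(r);
  }
  long long guard = 8 * V.total_size() + 64, steps = 0;
  while (!work.empty()) {
    Rng r = work.back();
    work.pop_back();
    if (++steps > guard) stop("malformed index: locate did not terminate");
    int ri = V.rec(r.v);
    if (ri < 0) stop("malformed index: missing record");
    // strip sampled positions, keep maximal unsampled subranges
    std::vector<std::pair<int, int> > sub;
    int a = r.lo;
    for (int i = r.lo; i <= r.hi; i++) {
      int s = V.sample_at(r.v, i);
      if (s >= 0) {
        out.push_back(s);
        if (a <= i - 1) sub.push_back(std::make_pair(a, i - 1));
        a = i + 1;
      }
    }
    if (a <= r.hi) sub.push_back(std::make_pair(a, r.hi));
    for (size_t q = 0; q < sub.size(); q++) {
      int lo = sub[q].first, hi = sub[q].second;
      // advance run by run
      long long pos = 0;
      for (int k = V.rptr[ri]; k < V.rptr[ri + 1]; k++) {
        int w = V.rsucc[k], len = V.rlen[k];
        long long rlo = pos, rhi = pos + len - 1;
        pos += len;
        if (rhi < lo) continue;
        if (rlo > hi) break;
        long long x = std::max<long long>(rlo, lo), y = std::min<long long>(rhi, hi);
        if (w <= 0) stop("malformed index: unsampled terminal position");
        long long nx = V.cum_rank(ri, w) + V.rank_in_body(ri, x, w);
        Rng nr;
        nr.v = w;
        nr.lo = (int)nx;
        nr.hi = (int)(nx + (y - x));
        work.push_back(nr);
      }
    }
  }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// successor -> count over a record range, successors ascending
// [[Rcpp::export]]
IntegerMatrix gbwt_range_succ_counts_cpp(List core, int node, int sp, int ep) {
  View V(core);
  int ri = V.rec(node);
  std::map<int, int> m;
  if (ri >= 0 && sp <= ep) {
    long long pos = 0;
    for (int k = V.rptr[ri]; k < V.rptr[ri + 1]; k++) {
      long long rlo = pos, rhi = pos + V.rlen[k] - 1;
      pos += V.rlen[k];
      if (rhi < sp) continue;
      if (rlo > ep) break;
      long long x = std::max<long long>(rlo, sp), y = std::min<long long>(rhi, ep);
      m[V.rsucc[k]] += (int)(y - x + 1);
    }
  }
  IntegerMatrix out(m.size(), 2);
  int i = 0;
  for (std::map<int, int>::const_iterator it = m.begin(); it != m.end(); ++it) {
    out(i, 0) = it->first;
    out(i, 1) = it->second;
    i++;
  }
  return out;
}
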