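// Structured-coalescent ancestral recombination graph engine.
//
// Simulates, backwards in time, the genealogy of haplotypes sampled from a
// two-population split demography in which a hard sweep (driven by a
// recorded forward-time allele-frequency trajectory) has just fixed in one
// population. Ploidy enters through the number of chromosome copies per
// individual, k: pairwise coalescence rate 1/(N*k) per generation within a
// population, and recombination acts on each lineage's recombinable span at
// rate r per bp per generation.
//
// During the sweep phase lineages in the selected population carry an
// allelic class (derived/ancestral at the selected site); coalescence is
// restricted to within-class pairs at rates 1/(x*N*k) and 1/((1-x)*N*k)
// where x is the trajectory frequency in that generation, and recombination
// between a lineage's material and the selected site reassigns the separated
// piece's class (derived with probability x). Events in the sweep phase are
// drawn generation by generation, exactly on the trajectory's time grid;
// neutral phases use continuous exponential waiting times.
//
// All randomness comes from R's RNG (unif_rand/exp_rand), so set.seed() in R
// governs reproducibility. The function returns a flat branch table
// (time interval, segment interval, descendant-leaf set in CSR layout) from
// which mutations are dropped on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<uint64_t> Mask;

struct Seg {
  double l, r;
  Mask m;
};

struct Lin {
  std::vector<Seg> segs;
  double birth;
  int pop;  // 0 = selected/focal population, 1 = other
  int cls;  // 0 = ancestral, 1 = derived (sweep phase, pop 0 only)
};

struct Rec {
  double t0, t1;
  std::vector<Seg> segs;
};

static inline int mask_count(const Mask& m) {
  int c = 0;
  for (uint64_t w : m) {
#ifdef __GNUC__
    c += __builtin_popcountll(w);
#else
    while (w) { c += (int)(w & 1); w >>= 1; }
#endif
  }
  return c;
}

static inline double runif01() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

static inline int rint_below(int n) {
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

class Engine {
public:
  Engine(int n1, int n2, double N, int k, double L, double sel_pos,
         double rec_rate, double max_events)
    : n1_(n1), n2_(n2), n_tot_(n1 + n2), N_(N), k_(k), L_(L),
      sel_pos_(sel_pos), rec_(rec_rate), max_events_(max_events),
      words_((n1 + n2 + 63) / 64), n_events_(0), t_last_(0.0) {
    for (int i = 0; i < n_tot_; ++i) {
      Lin x;
      Seg s;
      s.l = 0.0; s.r = L_;
      s.m.assign(words_, 0);
      s.m[i / 64] |= (uint64_t)1 << (i % 64);
      x.segs.push_back(s);
      x.birth = 0.0;
      x.pop = (i < n1_) ? 0 : 1;
      x.cls = 1;
      lin_.push_back(x);
    }
  }

  // --- phases ------------------------------------------------------------

  // Continuous-time neutral phase. two_pops: coalescence within pop labels
  // only. Runs until t_end (may be R_PosInf) or until everything has
  // coalesced. Returns the time reached.
  double neutral_phase(double t, double t_end, bool two_pops) {
    while (!lin_.empty()) {
      int c0 = 0, c1 = 0;
      double span = 0.0;
      for (const Lin& x : lin_) {
        if (x.pop == 0) ++c0; else ++c1;
        span += hull_span(x);
      }
      double rc0 = pair_count(two_pops ? c0 : (int)lin_.size()) / (N_ * k_);
      double rc1 = two_pops ? pair_count(c1) / (N_ * k_) : 0.0;
      if (!two_pops) { rc1 = 0.0; }
      double rr = rec_ * span;
      double tot = rc0 + rc1 + rr;
      if (tot <= 0.0) {  // nothing can happen before t_end
        return t_end;
      }
      double dt = exp_rand() / tot;
      if (t + dt >= t_end) return t_end;
      t += dt;
      t_last_ = t;
      bump_events();
      double u = unif_rand() * tot;
      if (u < rc0) {
        coalesce_random_pair(t, 0, two_pops);
      } else if (u < rc0 + rc1) {
        coalesce_random_pair(t, 1, true);
      } else {
        recombine_weighted(t, false, 0.0);
      }
    }
    return t;
  }

  // Discrete-generation sweep phase in pop 0; pop 1 evolves neutrally on the
  // same per-generation grid. traj is the forward-time frequency path
  // p_0..p_T (p_T = 1 at fixation); backwards generation j uses x = p_{T-j}.
  double sweep_phase(double t0, const NumericVector& traj) {
    int T = traj.size() - 1;
    for (int j = 1; j <= T; ++j) {
      double x = traj[T - j];
      double tg = t0 + j;
      t_last_ = tg;
      bump_events();

      // pop 0, derived class: hard bound (cannot exceed copy count), then
      // stochastic within-class coalescence
      class_coalesce(tg, 0, 1, x * N_ * k_);
      // pop 0, ancestral class
      if (x < 1.0) class_coalesce(tg, 0, 0, (1.0 - x) * N_ * k_);
      // pop 1, neutral
      class_coalesce(tg, 1, -1, N_ * k_);

      // recombination: iterate over a snapshot of current lineages
      int n_now = (int)lin_.size();
      for (int i = 0; i < n_now && i < (int)lin_.size(); ++i) {
        // lineages may be appended during the loop; splits replace index i,
        // so re-check bounds but do not process newly added lineages
        const Lin& x_i = lin_[i];
        bool in_sweep_pop = (x_i.pop == 0);
        double span = in_sweep_pop ? sweep_span(x_i) : hull_span(x_i);
        double pr = rec_ * span;
        if (pr > 0.0 && unif_rand() < pr) {
          if (in_sweep_pop) {
            recombine_lineage(i, tg, true, x);
          } else {
            recombine_lineage(i, tg, false, 0.0);
          }
        }
      }
      if (lin_.empty()) return tg;
    }
    // trajectory origin: the mutation exists in a single copy, so every
    // remaining derived lineage coalesces into the mutation's background,
    // and the survivor joins the ancestral class; the two populations merge
    double tg = t0 + T;
    force_class_down(tg, 0, 1, 1);
    for (Lin& x : lin_) { x.pop = 0; x.cls = 0; }
    return tg;
  }

  void finish_records() {
    // any survivors (should not happen: material fully coalesces) -- record
    for (const Lin& x : lin_) record(x, t_last_);
    lin_.clear();
  }

  int n_alive() const { return (int)lin_.size(); }
  double t_last() const { return t_last_; }

  List export_records() const {
    size_t nrow = 0;
    for (const Rec& r : recs_) nrow += r.segs.size();
    NumericVector t0(nrow), t1(nrow), left(nrow), right(nrow);
    std::vector<int> ptr(nrow + 1, 0);
    std::vector<int> car;
    size_t i = 0;
    for (const Rec& r : recs_) {
      for (const Seg& s : r.segs) {
        t0[i] = r.t0; t1[i] = r.t1; left[i] = s.l; right[i] = s.r;
        for (int b = 0; b < n_tot_; ++b) {
          if (s.m[b / 64] & ((uint64_t)1 << (b % 64))) car.push_back(b + 1);
        }
        ptr[i + 1] = (int)car.size();
        ++i;
      }
    }
    return List::create(
      _["t0"] = t0, _["t1"] = t1, _["left"] = left, _["right"] = right,
      _["carriers_ptr"] = IntegerVector(ptr.begin(), ptr.end()),
      _["carriers"] = IntegerVector(car.begin(), car.end()),
      _["n_leaves"] = n_tot_, _["tmrca"] = t_last_);
  }

private:
  int n1_, n2_, n_tot_;
  double N_;
  int k_;
  double L_, sel_pos_, rec_, max_events_;
  int words_;
  double n_events_, t_last_;
  std::vector<Lin> lin_;
  std::vector<Rec> recs_;

  static double pair_count(int n) { return n * (n - 1) / 2.0; }

  void bump_events() {
    if (++n_events_ > max_events_) stop("coalescent engine exceeded max_events");
  }

  double hull_span(const Lin& x) const {
    if (x.segs.empty()) return 0.0;
    return x.segs.back().r - x.segs.front().l;
  }

  double sweep_span(const Lin& x) const {
    if (x.segs.empty()) return 0.0;
    double l = std::min(x.segs.front().l, sel_pos_);
    double r = std::max(x.segs.back().r, sel_pos_);
    return r - l;
  }

  void record(const Lin& x, double t) {
    if (t > x.birth && !x.segs.empty()) {
      Rec r; r.t0 = x.birth; r.t1 = t; r.segs = x.segs;
      recs_.push_back(r);
    }
  }

  void drop(int i) {  // swap-remove
    lin_[i] = lin_.back();
    lin_.pop_back();
  }

  // merge lineages i and j at time t; new lineage inherits pop/cls of i
  void merge(int i, int j, double t) {
    const Lin& a = lin_[i];
    const Lin& b = lin_[j];
    record(a, t);
    record(b, t);
    Lin m;
    m.birth = t; m.pop = a.pop; m.cls = a.cls;
    m.segs = union_segs(a.segs, b.segs);
    if (i < j) { drop(j); drop(i); } else { drop(i); drop(j); }
    if (!m.segs.empty()) lin_.push_back(m);
  }

  std::vector<Seg> union_segs(const std::vector<Seg>& A,
                              const std::vector<Seg>& B) const {
    std::vector<double> cuts;
    cuts.reserve(2 * (A.size() + B.size()));
    for (const Seg& s : A) { cuts.push_back(s.l); cuts.push_back(s.r); }
    for (const Seg& s : B) { cuts.push_back(s.l); cuts.push_back(s.r); }
    std::sort(cuts.begin(), cuts.end());
    cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
    std::vector<Seg> out;
    size_t ia = 0, ib = 0;
    for (size_t c = 0; c + 1 < cuts.size(); ++c) {
      double x1 = cuts[c], x2 = cuts[c + 1];
      while (ia < A.size() && A[ia].r <= x1) ++ia;
      while (ib < B.size() && B[ib].r <= x1) ++ib;
      const Seg* sa = (ia < A.size() && A[ia].l <= x1) ? &A[ia] : 0;
      const Seg* sb = (ib < B.size() && B[ib].l <= x1) ? &B[ib] : 0;
      if (!sa && !sb) continue;
      Mask m(words_, 0);
      if (sa) for (int w = 0; w < words_; ++w) m[w] |= sa->m[w];
      if (sb) for (int w = 0; w < words_; ++w) m[w] |= sb->m[w];
      if (mask_count(m) == n_tot_) continue;  // locally coalesced: drop
      if (!out.empty() && out.back().r == x1 && out.back().m == m) {
        out.back().r = x2;
      } else {
        Seg s; s.l = x1; s.r = x2; s.m = m;
        out.push_back(s);
      }
    }
    return out;
  }

  // split lineage i at breakpoint bp. In the sweep phase (sweep=true) the
  // piece on the selected-site side keeps the class, the other piece draws
  // derived with probability x; a piece without ancestral material is
  // discarded. Outside the sweep phase bp always lies inside the material
  // hull and both pieces survive.
  void recombine_lineage(int i, double t, bool sweep, double x) {
    const Lin p = lin_[i];
    double bp;
    if (sweep) {
      double l = std::min(p.segs.front().l, sel_pos_);
      double r = std::max(p.segs.back().r, sel_pos_);
      bp = l + runif01() * (r - l);
    } else {
      double l = p.segs.front().l, r = p.segs.back().r;
      bp = l + runif01() * (r - l);
    }
    std::vector<Seg> Lpart, Rpart;
    for (const Seg& s : p.segs) {
      if (s.r <= bp) Lpart.push_back(s);
      else if (s.l >= bp) Rpart.push_back(s);
      else {
        Seg a = s, b = s; a.r = bp; b.l = bp;
        Lpart.push_back(a); Rpart.push_back(b);
      }
    }
    if (Lpart.empty() || Rpart.empty()) {
      if (!sweep) return;  // breakpoint did not separate material: no-op
      // all material on one side of bp; the selected site is on the other
      // side, so the whole material lineage changes background
      bool sel_left = (sel_pos_ < bp);
      bool material_on_sel_side =
        (sel_left && Rpart.empty()) || (!sel_left && Lpart.empty());
      if (material_on_sel_side) return;  // stays linked: no-op
      record(p, t);
      Lin q; q.birth = t; q.pop = p.pop;
      q.segs = Lpart.empty() ? Rpart : Lpart;
      q.cls = (unif_rand() < x) ? 1 : 0;
      lin_[i] = q;
      return;
    }
    record(p, t);
    Lin a, b;
    a.birth = b.birth = t;
    a.pop = b.pop = p.pop;
    a.segs = Lpart; b.segs = Rpart;
    if (sweep) {
      bool sel_left = (sel_pos_ < bp);
      int new_cls = (unif_rand() < x) ? 1 : 0;
      a.cls = sel_left ? p.cls : new_cls;
      b.cls = sel_left ? new_cls : p.cls;
    } else {
      a.cls = b.cls = p.cls;
    }
    lin_[i] = a;
    lin_.push_back(b);
  }

  void recombine_weighted(double t, bool sweep, double x) {
    double span = 0.0;
    for (const Lin& l : lin_) span += sweep ? sweep_span(l) : hull_span(l);
    double u = unif_rand() * span;
    for (int i = 0; i < (int)lin_.size(); ++i) {
      double s = sweep ? sweep_span(lin_[i]) : hull_span(lin_[i]);
      if (u < s) { recombine_lineage(i, t, sweep, x); return; }
      u -= s;
    }
  }

  void coalesce_random_pair(double t, int pop, bool by_pop) {
    std::vector<int> idx;
    for (int i = 0; i < (int)lin_.size(); ++i) {
      if (!by_pop || lin_[i].pop == pop) idx.push_back(i);
    }
    if (idx.size() < 2) return;
    int a = rint_below((int)idx.size());
    int b = rint_below((int)idx.size() - 1);
    if (b >= a) ++b;
    merge(idx[a], idx[b], t);
  }

  std::vector<int> class_members(int pop, int cls) const {
    std::vector<int> idx;
    for (int i = 0; i < (int)lin_.size(); ++i) {
      if (lin_[i].pop == pop && (cls < 0 || lin_[i].cls == cls)) {
        idx.push_back(i);
      }
    }
    return idx;
  }

  void merge_random_from(std::vector<int>& idx, double t) {
    int a = rint_below((int)idx.size());
    int b = rint_below((int)idx.size() - 1);
    if (b >= a) ++b;
    merge(idx[a], idx[b], t);
  }

  // one backwards generation of within-class coalescence: enforce the hard
  // copy-number bound, then Bernoulli pair-coalescence draws (re-drawn after
  // each event, allowing multiple mergers per generation)
  void class_coalesce(double t, int pop, int cls, double copies) {
    int bound = std::max(1, (int)std::ceil(copies - 1e-9));
    std::vector<int> idx = class_members(pop, cls);
    while ((int)idx.size() > bound) {
      merge_random_from(idx, t);
      idx = class_members(pop, cls);
    }
    while (idx.size() >= 2) {
      double pc = pair_count((int)idx.size()) / copies;
      if (pc < 1.0 && unif_rand() >= pc) break;
      merge_random_from(idx, t);
      idx = class_members(pop, cls);
    }
  }

  void force_class_down(double t, int pop, int cls, int target) {
    std::vector<int> idx = class_members(pop, cls);
    while ((int)idx.size() > target) {
      merge_random_from(idx, t);
      idx = class_members(pop, cls);
    }
  }
};

// [[Rcpp::export(name = ".sim_arg_cpp")]]
List sim_arg_cpp(int n1, int n2, double N, int k, double L, double sel_pos,
                 double rec_rate, double tau_post, NumericVector traj,
                 double split_gens, bool sweep, double max_events = 5e7) {
  if (n1 < 1) stop("need at least one sampled haplotype in population 1");
  if (n1 + n2 < 2) stop("need at least two sampled haplotypes in total");
  Engine e(n1, n2, N, k, L, sel_pos, rec_rate, max_events);
  double t = 0.0;
  if (sweep) {
    if (traj.size() < 2) stop("trajectory must span at least one generation");
    if (traj[traj.size() - 1] != 1.0) stop("trajectory is not fixed (p_T != 1)");
    if (tau_post > 0.0) t = e.neutral_phase(t, tau_post, true);
    if (e.n_alive() > 0) t = e.sweep_phase(t, traj);
  } else {
    if (split_gens > 0.0 && n2 > 0) t = e.neutral_phase(t, split_gens, true);
  }
  if (e.n_alive() > 0) t = e.neutral_phase(t, R_PosInf, false);
  e.finish_records();
  return e.export_records();
}
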