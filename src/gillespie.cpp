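// Event-driven (Gillespie) core of the adaptive two-type SIS process.
//
// Exact continuous-time simulation with three event channels:
//   recovery   : each infected node at rate mu
//   contagion  : each S-I link at rate beta * psi(type of S end)
//   rewiring   : each S-I link at rate omega; the S end reconnects to a
//                uniformly chosen eligible susceptible (not itself, not a
//                current neighbour); no eligible target => no-op
// The S-I link registry is maintained incrementally; selection within a
// channel is uniform, so each event costs O(degree) expected time.
// Randomness comes from R's RNG, so set.seed() on the R side makes runs
// reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

namespace {

struct SIRegistry {
  // directed key s -> i is unique per link (one S end, one I end)
  std::vector<std::pair<int, int>> links[2];  // indexed by S-end type (0/1)
  std::unordered_map<long long, std::pair<int, int>> pos;  // key -> (list, idx)
  long long n_nodes;

  explicit SIRegistry(long long n) : n_nodes(n) {}
  long long key(int s, int i) const { return (long long)s * n_nodes + i; }

  void add(int s, int i, int s_type01) {
    links[s_type01].push_back({s, i});
    pos[key(s, i)] = {s_type01, (int)links[s_type01].size() - 1};
  }
  void remove(int s, int i) {
    auto it = pos.find(key(s, i));
    if (it == pos.end()) stop("SI registry inconsistency: missing link");
    int lid = it->second.first, idx = it->second.second;
    auto &vec = links[lid];
    auto last = vec.back();
    vec[idx] = last;
    pos[key(last.first, last.second)] = {lid, idx};
    vec.pop_back();
    pos.erase(it);
  }
  size_t size() const { return links[0].size() + links[1].size(); }
};

inline int runif_int(int n) {
  // uniform on {0, ..., n-1}
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export(name = ".gillespie_core")]]
List gillespie_core(IntegerMatrix edges, IntegerVector type,
                    IntegerVector state, double beta, double psi_a,
                    double psi_b, double mu, double omega, double t_max,
                    double sample_interval, bool stop_on_extinction,
                    bool debug_check, bool record_events,
                    int max_recorded_events) {
  const int n = type.size();
  const long long nn = n;
  std::vector<char> typ(n), st(n);
  for (int i = 0; i < n; ++i) {
    typ[i] = (char)(type[i] - 1);  // 0 = A, 1 = B
    st[i] = (char)state[i];        // 0 = S, 1 = I
  }

  std::vector<std::vector<int>> adj(n);
  std::unordered_set<long long> edge_set;
  edge_set.reserve(edges.nrow() * 2);
  auto ekey = [nn](int a, int b) {
    return a < b ? (long long)a * nn + b : (long long)b * nn + a;
  };
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
    edge_set.insert(ekey(a, b));
  }

  // node bookkeeping: susceptible / infected lists with position indices
  std::vector<int> sus, inf, pos_in(n);
  for (int i = 0; i < n; ++i) {
    if (st[i]) { pos_in[i] = (int)inf.size(); inf.push_back(i); }
    else       { pos_in[i] = (int)sus.size(); sus.push_back(i); }
  }
  auto list_remove = [&](std::vector<int> &vec, int node) {
    int idx = pos_in[node], last = vec.back();
    vec[idx] = last;
    pos_in[last] = idx;
    vec.pop_back();
  };

  double deg_sum[2] = {0.0, 0.0};
  double n_type[2] = {0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    deg_sum[(int)typ[i]] += adj[i].size();
    n_type[(int)typ[i]] += 1.0;
  }

  SIRegistry reg(nn);
  for (int s = 0; s < n; ++s) {
    if (st[s]) continue;
    for (int nb : adj[s])
      if (st[nb]) reg.add(s, nb, typ[s]);
  }

  auto registry_audit = [&]() {
    size_t cnt = 0;
    for (int s = 0; s < n; ++s) {
      if (st[s]) continue;
      for (int nb : adj[s]) {
        if (!st[nb]) continue;
        ++cnt;
        auto it = reg.pos.find(reg.key(s, nb));
        if (it == reg.pos.end())
          stop("SI registry inconsistency: link absent from registry");
        if ((int)typ[s] != it->second.first)
          stop("SI registry inconsistency: link filed under wrong type");
      }
    }
    if (cnt != reg.size())
      stop("SI registry inconsistency: size mismatch");
  };

  const double psi[2] = {psi_a, psi_b};
  double t = 0.0;
  long long n_events = 0;
  bool extinct = inf.empty();
  double extinction_time = extinct ? 0.0 : NA_REAL;

  std::vector<double> out_t, out_ka, out_kb, out_si;
  std::vector<int> out_ia, out_ib;
  std::vector<double> ev_t;
  std::vector<int> ev_code, ev_node;

  auto sample_now = [&](double tt) {
    out_t.push_back(tt);
    int ia = 0, ib = 0;
    for (int x : inf) (typ[x] ? ib : ia)++;
    out_ia.push_back(ia);
    out_ib.push_back(ib);
    out_ka.push_back(n_type[0] > 0 ? deg_sum[0] / n_type[0] : NA_REAL);
    out_kb.push_back(n_type[1] > 0 ? deg_sum[1] / n_type[1] : NA_REAL);
    out_si.push_back((double)reg.size());
    if (debug_check) registry_audit();
  };

  double next_sample = 0.0;
  sample_now(0.0);
  next_sample = sample_interval;

  while (t < t_max) {
    double r_rec = mu * inf.size();
    double r_inf_a = beta * psi[0] * reg.links[0].size();
    double r_inf_b = beta * psi[1] * reg.links[1].size();
    double r_rew = omega * reg.size();
    double r_tot = r_rec + r_inf_a + r_inf_b + r_rew;
    if (r_tot <= 0.0) break;  // absorbing (extinct or frozen)

    double dt = -std::log(unif_rand()) / r_tot;
    double t_next = t + dt;
    while (next_sample <= std::min(t_next, t_max) + 1e-12 &&
           next_sample <= t_max + 1e-12) {
      sample_now(next_sample);
      next_sample += sample_interval;
    }
    if (t_next >= t_max) { t = t_max; break; }
    t = t_next;
    ++n_events;

    double u = unif_rand() * r_tot;
    int ev = -1, ev_n = -1;
    if (u < r_rec) {
      // recovery
      int x = inf[runif_int((int)inf.size())];
      list_remove(inf, x);
      st[x] = 0;
      pos_in[x] = (int)sus.size();
      sus.push_back(x);
      for (int nb : adj[x]) {
        if (st[nb]) reg.add(x, nb, typ[x]);       // x now S next to I
        else reg.remove(nb, x);                   // nb was S next to I=x
      }
      ev = 0; ev_n = x;
    } else if (u < r_rec + r_inf_a + r_inf_b) {
      // contagion along a uniformly chosen S-I link of the drawn S type
      int lid = (u < r_rec + r_inf_a) ? 0 : 1;
      auto &vec = reg.links[lid];
      auto link = vec[runif_int((int)vec.size())];
      int s = link.first;
      list_remove(sus, s);
      st[s] = 1;
      pos_in[s] = (int)inf.size();
      inf.push_back(s);
      for (int nb : adj[s]) {
        if (st[nb]) reg.remove(s, nb);            // incl. the focal link
        else reg.add(nb, s, typ[nb]);
      }
      ev = 1; ev_n = s;
    } else {
      // rewiring of a uniformly chosen S-I link
      int total = (int)reg.size();
      int idx = runif_int(total);
      int lid = idx < (int)reg.links[0].size() ? 0 : 1;
      if (lid == 1) idx -= (int)reg.links[0].size();
      auto link = reg.links[lid][idx];
      int s = link.first, i = link.second;
      int target = -1;
      int n_sus = (int)sus.size();
      for (int tries = 0; tries < 60 && n_sus > 1; ++tries) {
        int cand = sus[runif_int(n_sus)];
        if (cand != s && !edge_set.count(ekey(s, cand))) {
          target = cand;
          break;
        }
      }
      if (target < 0) {
        // exact fallback: enumerate eligible susceptibles
        std::vector<int> elig;
        for (int cand : sus)
          if (cand != s && !edge_set.count(ekey(s, cand)))
            elig.push_back(cand);
        if (!elig.empty()) target = elig[runif_int((int)elig.size())];
      }
      if (target >= 0) {
        // cut s-i
        edge_set.erase(ekey(s, i));
        auto drop = [&](int from, int what) {
          auto &v = adj[from];
          for (size_t j = 0; j < v.size(); ++j)
            if (v[j] == what) { v[j] = v.back(); v.pop_back(); return; }
          stop("adjacency inconsistency");
        };
        drop(s, i);
        drop(i, s);
        reg.remove(s, i);
        deg_sum[(int)typ[i]] -= 1.0;
        // connect s-target (both susceptible: no registry entry)
        edge_set.insert(ekey(s, target));
        adj[s].push_back(target);
        adj[target].push_back(s);
        deg_sum[(int)typ[target]] += 1.0;
        ev = 2; ev_n = s;
      } else {
        ev = 3; ev_n = s;  // no eligible target: no-op
      }
    }

    if (record_events && (int)ev_t.size() < max_recorded_events) {
      ev_t.push_back(t);
      ev_code.push_back(ev);
      ev_node.push_back(ev_n + 1);
    }

    if (inf.empty()) {
      extinct = true;
      extinction_time = t;
      if (stop_on_extinction) break;
    }
  }

  // emit remaining sample points (state is frozen after the last event)
  while (next_sample <= t_max + 1e-12) {
    sample_now(next_sample);
    next_sample += sample_interval;
  }

  // final edge list from adjacency
  IntegerMatrix final_edges((int)edge_set.size(), 2);
  {
    int r = 0;
    for (int a = 0; a < n; ++a)
      for (int b : adj[a])
        if (a < b) {
          final_edges(r, 0) = a + 1;
          final_edges(r, 1) = b + 1;
          ++r;
        }
  }
  IntegerVector final_state(n);
  for (int i = 0; i < n; ++i) final_state[i] = st[i];

  List samples = List::create(
      _["t"] = out_t, _["I_a"] = out_ia, _["I_b"] = out_ib,
      _["k_a"] = out_ka, _["k_b"] = out_kb, _["si_links"] = out_si);
  List events = R_NilValue;
  if (record_events)
    events = List::create(_["t"] = ev_t, _["code"] = ev_code,
                          _["node"] = ev_node);
  return List::create(_["samples"] = samples, _["edges"] = final_edges,
                      _["state"] = final_state, _["n_events"] = n_events,
                      _["extinct"] = extinct,
                      _["extinction_time"] = extinction_time,
                      _["t_end"] = std::min(t, t_max), _["events"] = events);
}
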