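// Vertex model of germband extension: free energy with area elasticity,
// perimeter contractility and per-class line tension (four tension laws),
// explicit Euler gradient flow and T1 edge swaps.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

struct Params {
  double eta, dt, d_min, p, K, A0, Gamma;
  double L_int, L_bdy, L_sup, log_floor, step_cap;
  int variant;
  bool chain_gradient;  // distribute log-L force over the whole chain
};

static Params read_params(const List& par) {
  Params q;
  q.eta = as<double>(par["eta"]);
  q.dt = as<double>(par["dt"]);
  q.d_min = as<double>(par["d_min"]);
  q.p = as<double>(par["p"]);
  q.K = as<double>(par["K"]);
  q.A0 = as<double>(par["A0"]);
  q.Gamma = as<double>(par["Gamma"]);
  q.L_int = as<double>(par["Lambda_int"]);
  q.L_bdy = as<double>(par["Lambda_bdy"]);
  q.L_sup = as<double>(par["Lambda_sup"]);
  q.log_floor = as<double>(par["log_floor"]);
  q.step_cap = as<double>(par["step_cap"]);
  q.variant = as<int>(par["variant"]);
  q.chain_gradient = as<bool>(par["chain_gradient"]);
  return q;
}

struct Mesh {
  std::vector<std::array<double,2>> V;
  std::vector<std::vector<int>> cells;  // 0-based vertex ids, CCW
  std::vector<int> ident;               // stripe identity 1..4 (0 = none)
};

static Mesh read_mesh(const NumericMatrix& V0, const List& cells0,
                      const IntegerVector& ident) {
  Mesh m;
  m.V.resize(V0.nrow());
  for (int i = 0; i < V0.nrow(); ++i) { m.V[i] = {V0(i,0), V0(i,1)}; }
  m.cells.resize(cells0.size());
  for (int c = 0; c < cells0.size(); ++c) {
    IntegerVector vv = cells0[c];
    m.cells[c].assign(vv.begin(), vv.end());
    for (auto& x : m.cells[c]) x -= 1;  // to 0-based
  }
  m.ident.assign(ident.begin(), ident.end());
  return m;
}

struct Edge {
  int a, b;       // vertex ids (a < b)
  int c1, c2;     // adjacent cells; c2 = -1 on the tissue border
  double len;
  int cls;        // 0 = linear Lambda_int, 1 = boundary, 2 = skipped
  double L;       // chain length for log-L laws
  int chain_cell; // cell whose contiguous boundary run defines L
  int chain_id;   // run index within that cell
};

struct Topo {
  std::vector<Edge> edges;
  std::vector<std::vector<int>> cellEdges;   // edge indices per cell, in order
  std::vector<std::vector<int>> vcells;      // incident cells per vertex
  // contiguous boundary runs: per cell, list of (edge indices, total length)
  std::vector<std::vector<std::vector<int>>> runs;
  std::vector<std::vector<double>> runSums;
};

static int edge_class(const Mesh& m, int c1, int c2, int variant) {
  if (c2 < 0) return 0;
  int ia = m.ident[c1], ib = m.ident[c2];
  if (ia <= 0 || ib <= 0 || ia == ib) return 0;
  int d = std::abs(ia - ib); d = std::min(d, 4 - d);
  if (d == 2 && variant == 4) return 2;
  return 1;
}

static void build_topo(const Mesh& m, const Params& q, Topo& T) {
  const int nv = (int)m.V.size();
  const int nc = (int)m.cells.size();
  T.edges.clear();
  T.cellEdges.assign(nc, {});
  T.vcells.assign(nv, {});
  std::map<long long,int> key2e;
  for (int c = 0; c < nc; ++c) {
    const auto& poly = m.cells[c];
    int k = (int)poly.size();
    T.cellEdges[c].resize(k);
    for (int t = 0; t < k; ++t) {
      int v = poly[t], w = poly[(t+1)%k];
      T.vcells[v].push_back(c);
      int a = std::min(v,w), b = std::max(v,w);
      long long key = (long long)a * nv + b;
      auto it = key2e.find(key);
      int ei;
      if (it == key2e.end()) {
        Edge e; e.a = a; e.b = b; e.c1 = c; e.c2 = -1;
        double dx = m.V[b][0]-m.V[a][0], dy = m.V[b][1]-m.V[a][1];
        e.len = std::sqrt(dx*dx+dy*dy);
        e.cls = 0; e.L = e.len; e.chain_cell = -1; e.chain_id = -1;
        ei = (int)T.edges.size();
        T.edges.push_back(e);
        key2e[key] = ei;
      } else {
        ei = it->second;
        if (T.edges[ei].c2 != -1) stop("edge shared by more than two cells");
        T.edges[ei].c2 = c;
      }
      T.cellEdges[c][t] = ei;
    }
  }
  for (auto& e : T.edges) e.cls = edge_class(m, e.c1, e.c2, q.variant);
  // dedupe vertex-cell incidence (each cell touches a vertex once)
  for (auto& vc : T.vcells) {
    std::sort(vc.begin(), vc.end());
    vc.erase(std::unique(vc.begin(), vc.end()), vc.end());
  }
  // contiguous boundary runs per cell, for the log-L tension laws
  if (q.variant >= 3) {
    T.runs.assign(nc, {});
    T.runSums.assign(nc, {});
    std::vector<std::vector<int>> runIdOfEdge(nc);
    for (int c = 0; c < nc; ++c) {
      const auto& ce = T.cellEdges[c];
      int k = (int)ce.size();
      std::vector<bool> bd(k);
      bool allb = true, anyb = false;
      for (int t = 0; t < k; ++t) {
        bd[t] = T.edges[ce[t]].cls >= 1;
        allb = allb && bd[t];
        anyb = anyb || bd[t];
      }
      if (!anyb) continue;
      std::vector<std::vector<int>>& rr = T.runs[c];
      std::vector<double>& ss = T.runSums[c];
      if (allb) {
        std::vector<int> run(ce.begin(), ce.end());
        double s = 0; for (int e : run) s += T.edges[e].len;
        rr.push_back(run); ss.push_back(s);
      } else {
        int start = 0;
        while (bd[(start+k-1)%k] && start < k) ++start; // first run start
        // scan k positions from 'start'
        int t = 0;
        while (t < k) {
          int pos = (start + t) % k;
          if (!bd[pos]) { ++t; continue; }
          std::vector<int> run;
          double s = 0;
          while (t < k) {
            int pp = (start + t) % k;
            if (!bd[pp]) break;
            run.push_back(ce[pp]);
            s += T.edges[ce[pp]].len;
            ++t;
          }
          rr.push_back(run); ss.push_back(s);
        }
      }
      // map edges to run ids for this cell
      for (size_t r = 0; r < rr.size(); ++r) {
        for (int e : rr[r]) {
          Edge& E = T.edges[e];
          double s = ss[r];
          int side = (E.chain_cell == -1) ? 0 : 1;
          if (side == 0) {
            E.L = s; E.chain_cell = c; E.chain_id = (int)r;
          } else {
            // second cell's run: keep the smaller sum (tie: lower cell id,
            // i.e. the first assignment since cells are scanned in order)
            if (s < E.L - 1e-15) {
              E.L = s; E.chain_cell = c; E.chain_id = (int)r;
            }
          }
        }
      }
    }
  }
}

static double poly_area(const Mesh& m, const std::vector<int>& poly) {
  double a = 0;
  int k = (int)poly.size();
  for (int t = 0; t < k; ++t) {
    const auto& p = m.V[poly[t]];
    const auto& qv = m.V[poly[(t+1)%k]];
    a += p[0]*qv[1] - qv[0]*p[1];
  }
  return a/2;
}

static double poly_perim(const Mesh& m, const std::vector<int>& poly) {
  double s = 0;
  int k = (int)poly.size();
  for (int t = 0; t < k; ++t) {
    const auto& p = m.V[poly[t]];
    const auto& qv = m.V[poly[(t+1)%k]];
    double dx = qv[0]-p[0], dy = qv[1]-p[1];
    s += std::sqrt(dx*dx+dy*dy);
  }
  return s;
}

static double tension_energy_edge(const Edge& e, const Params& q) {
  double lam_b = (e.cls == 2) ? q.L_sup : q.L_bdy;
  switch (q.variant) {
    case 1:
      return (e.cls >= 1 ? lam_b : q.L_int) * e.len;
    case 2:
      if (e.cls >= 1) return lam_b * std::log(std::max(e.len, q.log_floor));
      return q.L_int * e.len;
    default:
      if (e.cls >= 1) return lam_b * std::log(std::max(e.L, q.log_floor));
      return q.L_int * e.len;
  }
}

static double total_energy(const Mesh& m, const Topo& T, const Params& q) {
  double U = 0;
  for (const auto& poly : m.cells) {
    double A = poly_area(m, poly);
    double P = poly_perim(m, poly);
    U += 0.5*q.K*(A-q.A0)*(A-q.A0) + 0.5*q.Gamma*P*P;
  }
  for (const auto& e : T.edges) U += tension_energy_edge(e, q);
  return U;
}

static void add_forces(const Mesh& m, const Topo& T, const Params& q,
                       std::vector<std::array<double,2>>& F) {
  const int nc = (int)m.cells.size();
  // area elasticity and perimeter contractility
  for (int c = 0; c < nc; ++c) {
    const auto& poly = m.cells[c];
    int k = (int)poly.size();
    double A = poly_area(m, poly);
    double P = poly_perim(m, poly);
    double ka = q.K*(A-q.A0);
    double gp = q.Gamma*P;
    for (int t = 0; t < k; ++t) {
      int ip = poly[(t+k-1)%k], ic = poly[t], in = poly[(t+1)%k];
      // dA/dr_i = ((y_next - y_prev)/2, (x_prev - x_next)/2)
      F[ic][0] -= ka * 0.5 * (m.V[in][1] - m.V[ip][1]);
      F[ic][1] -= ka * 0.5 * (m.V[ip][0] - m.V[in][0]);
      // dP/dr_i = unit(r_i - r_prev) + unit(r_i - r_next)
      double dxp = m.V[ic][0]-m.V[ip][0], dyp = m.V[ic][1]-m.V[ip][1];
      double dxn = m.V[ic][0]-m.V[in][0], dyn = m.V[ic][1]-m.V[in][1];
      double lp = std::sqrt(dxp*dxp+dyp*dyp), ln = std::sqrt(dxn*dxn+dyn*dyn);
      if (lp > 1e-14) { F[ic][0] -= gp*dxp/lp; F[ic][1] -= gp*dyp/lp; }
      if (ln > 1e-14) { F[ic][0] -= gp*dxn/ln; F[ic][1] -= gp*dyn/ln; }
    }
  }
  // line tension
  for (const auto& e : T.edges) {
    double lam_b = (e.cls == 2) ? q.L_sup : q.L_bdy;
    bool logl = (q.variant == 2 && e.cls >= 1);
    bool logL = (q.variant >= 3 && e.cls >= 1);
    if (q.variant == 1 || e.cls == 0) {
      double lam = (e.cls >= 1 && q.variant == 1) ? lam_b : q.L_int;
      if (e.len > 1e-14) {
        double ux = (m.V[e.a][0]-m.V[e.b][0])/e.len;
        double uy = (m.V[e.a][1]-m.V[e.b][1])/e.len;
        F[e.a][0] -= lam*ux; F[e.a][1] -= lam*uy;
        F[e.b][0] += lam*ux; F[e.b][1] += lam*uy;
      }
    } else if (logl) {
      double l = std::max(e.len, q.log_floor);
      double coef = lam_b / l;
      if (e.len > 1e-14) {
        double ux = (m.V[e.a][0]-m.V[e.b][0])/e.len;
        double uy = (m.V[e.a][1]-m.V[e.b][1])/e.len;
        F[e.a][0] -= coef*ux; F[e.a][1] -= coef*uy;
        F[e.b][0] += coef*ux; F[e.b][1] += coef*uy;
      }
    } else if (logL) {
      double L = std::max(e.L, q.log_floor);
      double coef = lam_b / L;
      if (q.chain_gradient) {
        // exact gradient: the edge's energy Lambda*log(L) pulls on every
        // edge of its defining chain
        const auto& run = T.runs[e.chain_cell][e.chain_id];
        for (int ei : run) {
          const Edge& ee = T.edges[ei];
          if (ee.len <= 1e-14) continue;
          double ux = (m.V[ee.a][0]-m.V[ee.b][0])/ee.len;
          double uy = (m.V[ee.a][1]-m.V[ee.b][1])/ee.len;
          F[ee.a][0] -= coef*ux; F[ee.a][1] -= coef*uy;
          F[ee.b][0] += coef*ux; F[ee.b][1] += coef*uy;
        }
      } else {
        // local tension: the edge carries tension Lambda/L along itself
        // (the chain length enters as a frozen coefficient)
        if (e.len > 1e-14) {
          double ux = (m.V[e.a][0]-m.V[e.b][0])/e.len;
          double uy = (m.V[e.a][1]-m.V[e.b][1])/e.len;
          F[e.a][0] -= coef*ux; F[e.a][1] -= coef*uy;
          F[e.b][0] += coef*ux; F[e.b][1] += coef*uy;
        }
      }
    }
  }
}

// remove one value from a polygon's vertex list
static void poly_remove(std::vector<int>& poly, int v) {
  poly.erase(std::remove(poly.begin(), poly.end(), v), poly.end());
}

static bool cell_has_edge(const std::vector<int>& poly, int x, int y) {
  int k = (int)poly.size();
  for (int t = 0; t < k; ++t) {
    int v = poly[t], w = poly[(t+1)%k];
    if ((v==x && w==y) || (v==y && w==x)) return true;
  }
  return false;
}

// single sweep of T1 swaps; returns number performed, appends event rows
static int t1_pass(Mesh& m, const Params& q, double tnow,
                   std::vector<std::array<double,6>>& log,
                   int& suppressed) {
  int nswap = 0;
  bool again = true;
  int guard = 0;
  while (again && guard < 100) {
    again = false;
    ++guard;
    Topo T;
    build_topo(m, q, T);
    for (const auto& e : T.edges) {
      if (e.c2 < 0 || e.len >= q.d_min) continue;
      int i = e.a, j = e.b;
      if (T.vcells[i].size() != 3 || T.vcells[j].size() != 3) {
        ++suppressed; continue;   // border or higher-order vertex: unresolved
      }
      int C = e.c1, D = e.c2;
      int A = -1, B = -1;
      for (int c : T.vcells[i]) if (c != C && c != D) A = c;
      for (int c : T.vcells[j]) if (c != C && c != D) B = c;
      if (A < 0 || B < 0 || A == B) { ++suppressed; continue; }
      if ((int)m.cells[C].size() <= 3 || (int)m.cells[D].size() <= 3) {
        ++suppressed; continue;
      }
      // geometry: rotate the edge 90 degrees about its midpoint
      double mx = (m.V[i][0]+m.V[j][0])/2, my = (m.V[i][1]+m.V[j][1])/2;
      double dx = m.V[j][0]-m.V[i][0], dy = m.V[j][1]-m.V[i][1];
      double l = std::sqrt(dx*dx+dy*dy);
      double nx, ny;
      if (l > 1e-14) { nx = -dy/l; ny = dx/l; } else { nx = 1; ny = 0; }
      double h = q.p*q.d_min/2;
      // centroid of C decides which side keeps vertex i
      double cx = 0, cy = 0;
      for (int v : m.cells[C]) { cx += m.V[v][0]; cy += m.V[v][1]; }
      cx /= m.cells[C].size(); cy /= m.cells[C].size();
      double s = nx*(cx-mx) + ny*(cy-my);
      double sgn = (s >= 0) ? 1.0 : -1.0;
      std::array<double,2> posC = {mx + sgn*h*nx, my + sgn*h*ny};
      std::array<double,2> posD = {mx - sgn*h*nx, my - sgn*h*ny};
      // locate neighbours of i in A and of j in B before touching topology
      int ia = -1, jb = -1, x = -1, u = -1;
      bool xi_in_C = false, uj_in_D = false;
      if (A >= 0) {
        std::vector<int>& pa = m.cells[A];
        int ka = (int)pa.size();
        for (int t = 0; t < ka; ++t) if (pa[t] == i) ia = t;
        if (ia < 0) { ++suppressed; continue; }
        x = pa[(ia+ka-1)%ka];              // predecessor of i in A
        xi_in_C = cell_has_edge(m.cells[C], x, i);
      }
      if (B >= 0) {
        std::vector<int>& pb = m.cells[B];
        int kb = (int)pb.size();
        for (int t = 0; t < kb; ++t) if (pb[t] == j) jb = t;
        if (jb < 0) { ++suppressed; continue; }
        u = pb[(jb+kb-1)%kb];              // predecessor of j in B
        uj_in_D = cell_has_edge(m.cells[D], u, j);
      }
      // rewire
      poly_remove(m.cells[C], j);
      poly_remove(m.cells[D], i);
      if (A >= 0) {
        std::vector<int>& pa = m.cells[A];
        if (xi_in_C) pa.insert(pa.begin()+ia+1, j); // ..., x, i, j, ...
        else pa.insert(pa.begin()+ia, j);           // ..., x, j, i, ...
      }
      if (B >= 0) {
        std::vector<int>& pb = m.cells[B];
        if (uj_in_D) pb.insert(pb.begin()+jb+1, i); // ..., u, j, i, ...
        else pb.insert(pb.begin()+jb, i);           // ..., u, i, j, ...
      }
      m.V[i] = posC;
      m.V[j] = posD;
      log.push_back({tnow, (double)(C+1), (double)(D+1),
                     (double)(A+1), (double)(B+1), l});
      ++nswap;
      again = true;
      break;  // topology changed: rebuild and rescan
    }
  }
  return nswap;
}

static List mesh_cells_out(const Mesh& m) {
  List cl(m.cells.size());
  for (size_t c = 0; c < m.cells.size(); ++c) {
    IntegerVector vv(m.cells[c].size());
    for (size_t t = 0; t < m.cells[c].size(); ++t) vv[t] = m.cells[c][t]+1;
    cl[c] = vv;
  }
  return cl;
}

static NumericMatrix mesh_V_out(const Mesh& m) {
  NumericMatrix V((int)m.V.size(), 2);
  for (size_t i = 0; i < m.V.size(); ++i) { V(i,0)=m.V[i][0]; V(i,1)=m.V[i][1]; }
  return V;
}

// [[Rcpp::export]]
double vm_energy_cpp(NumericMatrix V0, List cells0, IntegerVector ident,
                     List par) {
  Params q = read_params(par);
  Mesh m = read_mesh(V0, cells0, ident);
  Topo T;
  build_topo(m, q, T);
  return total_energy(m, T, q);
}

// [[Rcpp::export]]
NumericMatrix vm_force_cpp(NumericMatrix V0, List cells0, IntegerVector ident,
                           List par) {
  Params q = read_params(par);
  Mesh m = read_mesh(V0, cells0, ident);
  Topo T;
  build_topo(m, q, T);
  std::vector<std::array<double,2>> F(m.V.size(), {0,0});
  add_forces(m, T, q, F);
  NumericMatrix out((int)F.size(), 2);
  for (size_t i = 0; i < F.size(); ++i) { out(i,0)=F[i][0]; out(i,1)=F[i][1]; }
  return out;
}

// [[Rcpp::export]]
DataFrame vm_edges_cpp(NumericMatrix V0, List cells0, IntegerVector ident,
                       List par) {
  Params q = read_params(par);
  Mesh m = read_mesh(V0, cells0, ident);
  Topo T;
  build_topo(m, q, T);
  int ne = (int)T.edges.size();
  IntegerVector a(ne), b(ne), c1(ne), c2(ne), cls(ne);
  NumericVector len(ne), L(ne), f(ne);
  for (int k = 0; k < ne; ++k) {
    const Edge& e = T.edges[k];
    a[k]=e.a+1; b[k]=e.b+1; c1[k]=e.c1+1;
    c2[k]= e.c2 < 0 ? NA_INTEGER : e.c2+1;
    cls[k]=e.cls; len[k]=e.len; L[k]=e.L;
    f[k]=tension_energy_edge(e, q);
  }
  return DataFrame::create(_["v1"]=a, _["v2"]=b, _["cell_a"]=c1,
                           _["cell_b"]=c2, _["class"]=cls, _["length"]=len,
                           _["chain_length"]=L, _["tension_energy"]=f);
}

// [[Rcpp::export]]
List vm_t1_cpp(NumericMatrix V0, List cells0, IntegerVector ident, List par) {
  Params q = read_params(par);
  Mesh m = read_mesh(V0, cells0, ident);
  std::vector<std::array<double,6>> lg;
  int suppressed = 0;
  int n = t1_pass(m, q, 0.0, lg, suppressed);
  NumericMatrix lgm((int)lg.size(), 6);
  for (size_t r = 0; r < lg.size(); ++r)
    for (int c = 0; c < 6; ++c) lgm(r,c) = lg[r][c];
  return List::create(_["V"]=mesh_V_out(m), _["cells"]=mesh_cells_out(m),
                      _["n_swaps"]=n, _["suppressed"]=suppressed,
                      _["log"]=lgm);
}

// [[Rcpp::export]]
List vm_simulate_cpp(NumericMatrix V0, List cells0, IntegerVector ident,
                     List par, double t_end, double record_dt,
                     bool relax, double relax_tol, double energy_dt) {
  Params q = read_params(par);
  if (relax) { q.variant = 1; q.L_bdy = q.L_int; q.L_sup = q.L_int; }
  Mesh m = read_mesh(V0, cells0, ident);
  const int nv = (int)m.V.size();
  std::vector<std::array<double,6>> t1log;
  int suppressed = 0;
  std::vector<NumericMatrix> recV;
  std::vector<List> recC;
  std::vector<double> recT;
  std::vector<double> enT, enU;
  double t = 0;
  long nsteps = (long)std::ceil(t_end / q.dt);
  long rec_every = record_dt > 0 ? std::max(1L,(long)std::round(record_dt/q.dt))
                                 : nsteps + 1;
  long en_every = energy_dt > 0 ? std::max(1L,(long)std::round(energy_dt/q.dt))
                                : nsteps + 1;
  recV.push_back(mesh_V_out(m));
  recC.push_back(mesh_cells_out(m));
  recT.push_back(0.0);
  std::vector<std::array<double,2>> F(nv, {0,0});
  for (long step = 1; step <= nsteps; ++step) {
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
    if (!relax) t1_pass(m, q, t, t1log, suppressed);
    Topo T;
    build_topo(m, q, T);
    for (auto& f : F) { f[0]=0; f[1]=0; }
    add_forces(m, T, q, F);
    // cap per-step displacement: unbounded log forces can only arise
    // transiently on edges held below d_min by a suppressed swap, and the
    // cap keeps the integration finite there
    double dmax = q.step_cap;
    double maxf = 0;
    for (int i = 0; i < nv; ++i) {
      double sx = q.dt/q.eta * F[i][0], sy = q.dt/q.eta * F[i][1];
      double sn = std::sqrt(sx*sx + sy*sy);
      if (sn > dmax) { sx *= dmax/sn; sy *= dmax/sn; }
      m.V[i][0] += sx;
      m.V[i][1] += sy;
      double fn = std::sqrt(F[i][0]*F[i][0]+F[i][1]*F[i][1]);
      if (fn > maxf) maxf = fn;
      if (!std::isfinite(m.V[i][0]) || !std::isfinite(m.V[i][1]))
        stop("vertex position became non-finite at t = %f", t);
    }
    t = step * q.dt;
    if (step % en_every == 0) {
      enT.push_back(t);
      enU.push_back(total_energy(m, T, q));
    }
    if (step % rec_every == 0) {
      recV.push_back(mesh_V_out(m));
      recC.push_back(mesh_cells_out(m));
      recT.push_back(t);
    }
    if (relax && maxf/q.eta < relax_tol) break;
  }
  // always record the final state
  if (recT.back() < t - 1e-12) {
    recV.push_back(mesh_V_out(m));
    recC.push_back(mesh_cells_out(m));
    recT.push_back(t);
  }
  NumericMatrix lgm((int)t1log.size(), 6);
  for (size_t r = 0; r < t1log.size(); ++r)
    for (int c = 0; c < 6; ++c) lgm(r,c) = t1log[r][c];
  List RV(recV.size()), RC(recC.size());
  for (size_t k = 0; k < recV.size(); ++k) { RV[k]=recV[k]; RC[k]=recC[k]; }
  return List::create(
    _["V"] = RV, _["cells"] = RC, _["times"] = wrap(recT),
    _["t1_log"] = lgm, _["suppressed"] = suppressed,
    _["energy_times"] = wrap(enT), _["energy"] = wrap(enU),
    _["final_V"] = mesh_V_out(m), _["final_cells"] = mesh_cells_out(m),
    _["t_final"] = t);
}
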