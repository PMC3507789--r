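// Seeded ungapped protein-vs-translated-genome alignment.
//
// The genome is translated in six frames on the R side; this file only sees
// amino-acid strings. For each query we look up exact 4-mer seed matches in a
// word index of the subject frames, group seeds by diagonal, and run an
// ungapped X-drop extension with BLOSUM62 scoring. Gapped alignment is out of
// scope: indels and introns intentionally break hits into separate HSPs,
// which is exactly what the downstream HSP-pair classifier consumes.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const char AA_ALPHABET[] = "ARNDCQEGHILKMFPSTWYVBZX*";
static const int AA_N = 24;

// BLOSUM62, rows/cols in AA_ALPHABET order.
static const int BLOSUM62[AA_N][AA_N] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0,-4},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0,-1,-4},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0,-1,-4},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3,-2,-4},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3,-1,-4},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2,-1,-4},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0,-1,-4},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3,-1,-4},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3,-1,-4},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1,-1,-4},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1,-1,-4},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3,-1,-4},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1,-2,-4},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0,-4},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0,-4},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3,-2,-4},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2,-1,-4},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2,-1,-4},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1,-1,-4},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4,-1,-4},
  { 0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1,-1,-1,-4},
  {-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4,-4, 1}
};

static inline int aa_code(char c) {
  switch (c) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;
    case 'D': return 3;  case 'C': return 4;  case 'Q': return 5;
    case 'E': return 6;  case 'G': return 7;  case 'H': return 8;
    case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14;
    case 'S': return 15; case 'T': return 16; case 'W': return 17;
    case 'Y': return 18; case 'V': return 19; case 'B': return 20;
    case 'Z': return 21; case 'X': return 22; case '*': return 23;
    default:  return 22; // unknown -> X
  }
}

struct Hit {
  int query, subject;    // 0-based indices into the input vectors
  int qstart, qend;      // 0-based half-open, amino acids
  int sstart, send;      // 0-based half-open, amino acids
  int score;
};

// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(CharacterVector queries, CharacterVector subjects,
                          int word = 4, int xdrop = 40, int min_score = 40) {
  const int WORD_SPACE = 24 * 24 * 24 * 24;
  std::vector<std::string> subj(subjects.size());
  std::vector<std::vector<int>> subj_code(subjects.size());
  for (int s = 0; s < subjects.size(); ++s) {
    subj[s] = as<std::string>(subjects[s]);
    subj_code[s].resize(subj[s].size());
    for (size_t i = 0; i < subj[s].size(); ++i)
      subj_code[s][i] = aa_code(subj[s][i]);
  }

  // word index over all subjects: key -> flat list of (subject, position)
  std::vector<int> bucket_head(WORD_SPACE, -1);
  std::vector<int> next_entry;  // linked list of entries
  std::vector<std::pair<int,int>> entry_pos;
  for (int s = 0; s < (int)subj.size(); ++s) {
    const std::vector<int>& sc = subj_code[s];
    if ((int)sc.size() < word) continue;
    for (int i = 0; i + word <= (int)sc.size(); ++i) {
      bool clean = true;
      int key = 0;
      for (int k = 0; k < word; ++k) {
        int c = sc[i + k];
        if (c >= 22) { clean = false; break; } // skip X and *
        key = key * 24 + c;
      }
      if (!clean) continue;
      entry_pos.push_back(std::make_pair(s, i));
      next_entry.push_back(bucket_head[key]);
      bucket_head[key] = (int)entry_pos.size() - 1;
    }
  }

  std::vector<Hit> hits;
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    int qlen = (int)qs.size();
    if (qlen < word) continue;
    std::vector<int> qc(qlen);
    for (int i = 0; i < qlen; ++i) qc[i] = aa_code(qs[i]);

    // seeds grouped by (subject, diagonal); remember covered query ranges so
    // seeds inside an already-extended HSP are skipped
    std::vector<std::tuple<long long,int,int>> seeds; // (subj*BIG + diag, qpos, spos)
    for (int i = 0; i + word <= qlen; ++i) {
      bool clean = true;
      int key = 0;
      for (int k = 0; k < word; ++k) {
        int c = qc[i + k];
        if (c >= 22) { clean = false; break; }
        key = key * 24 + c;
      }
      if (!clean) continue;
      for (int e = bucket_head[key]; e != -1; e = next_entry[e]) {
        int s = entry_pos[e].first, si = entry_pos[e].second;
        long long diag_key = (long long)s * 4000000000LL +
                             (long long)(si - i + 1000000000);
        seeds.push_back(std::make_tuple(diag_key, i, si));
      }
    }
    std::sort(seeds.begin(), seeds.end());

    long long cur_diag = -1;
    int covered_qend = -1;
    for (size_t t = 0; t < seeds.size(); ++t) {
      long long dk = std::get<0>(seeds[t]);
      int qi = std::get<1>(seeds[t]);
      int si = std::get<2>(seeds[t]);
      if (dk != cur_diag) { cur_diag = dk; covered_qend = -1; }
      if (qi < covered_qend) continue;
      int s = (int)(dk / 4000000000LL);
      const std::vector<int>& sc = subj_code[s];
      int slen = (int)sc.size();

      // score the seed word
      int score = 0;
      for (int k = 0; k < word; ++k) score += BLOSUM62[qc[qi + k]][sc[si + k]];

      // extend right
      int best = score, best_qend = qi + word;
      int cur = score;
      for (int k = word; qi + k < qlen && si + k < slen; ++k) {
        cur += BLOSUM62[qc[qi + k]][sc[si + k]];
        if (cur > best) { best = cur; best_qend = qi + k + 1; }
        if (cur < best - xdrop) break;
      }
      // extend left
      int total_best = best, best_qstart = qi;
      cur = best;
      for (int k = 1; qi - k >= 0 && si - k >= 0; ++k) {
        cur += BLOSUM62[qc[qi - k]][sc[si - k]];
        if (cur > total_best) { total_best = cur; best_qstart = qi - k; }
        if (cur < total_best - xdrop) break;
      }
      covered_qend = best_qend;
      if (total_best >= min_score) {
        Hit h;
        h.query = q; h.subject = s;
        h.qstart = best_qstart; h.qend = best_qend;
        h.sstart = si - (qi - best_qstart); h.send = si + (best_qend - qi);
        h.score = total_best;
        hits.push_back(h);
      }
    }
  }

  int n = (int)hits.size();
  IntegerVector query(n), subject(n), qstart(n), qend(n), sstart(n), send(n),
      score(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].query + 1;     // 1-based indices for R
    subject[i] = hits[i].subject + 1;
    qstart[i] = hits[i].qstart + 1;   // 1-based inclusive aa coords
    qend[i] = hits[i].qend;
    sstart[i] = hits[i].sstart;       // 0-based half-open aa coords
    send[i] = hits[i].send;
    score[i] = hits[i].score;
  }
  return DataFrame::create(
      _["query"] = query, _["subject"] = subject,
      _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send,
      _["score"] = score);
}
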