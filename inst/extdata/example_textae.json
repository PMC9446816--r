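[
  {
    "pmid": "SYN00001",
    "sent_id": 0,
    "text": "GENE45 inhibits MIR111",
    "denotations": [
      {
        "id": "T1",
        "span": {
          "begin": 0,
          "end": 6
        },
        "obj": "gene"
      },
      {
        "id": "T2",
        "span": {
          "begin": 16,
          "end": 22
        },
        "obj": "rna"
      }
    ],
    "relations": [
      {
        "id": "R1",
        "pred": "negative_cause",
        "subj": "T1",
        "obj": "T2"
      }
    ]
  },
  {
    "pmid": "SYN00001",
    "sent_id": 1,
    "text": "PROT58 correlates with PROT98 in a dose dependent manner",
    "denotations": [
      {
        "id": "T1",
        "span": {
          "begin": 0,
          "end": 6
        },
        "obj": "protein"
      },
      {
        "id": "T2",
        "span": {
          "begin": 23,
          "end": 29
        },
        "obj": "protein"
      }
    ],
    "relations": [
      {
        "id": "R1",
        "pred": "undirected_link",
        "subj": "T1",
        "obj": "T2"
      }
    ]
  },
  {
    "pmid": "SYN00001",
    "sent_id": 2,
    "text": "PROT138 binds PROT182 levels in a dose dependent manner",
    "denotations": [
      {
        "id": "T1",
        "span": {
          "begin": 0,
          "end": 7
        },
        "obj": "protein"
      },
      {
        "id": "T2",
        "span": {
          "begin": 14,
          "end": 28
        },
        "obj": "protein"
      }
    ],
    "relations": [
      {
        "id": "R1",
        "pred": "undirected_link",
        "subj": "T1",
        "obj": "T2"
      }
    ]
  }
]
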