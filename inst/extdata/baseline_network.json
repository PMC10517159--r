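{
  "gain": 1,
  "inputs": {
    "c": 0.1,
    "a": 0.1,
    "b": 0.4
  },
  "nodes": [
    {
      "name": "cdh11",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "c",
          "weight": 1
        }
      ],
      "inhibitors": []
    },
    {
      "name": "pdgfrA",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "a",
          "weight": 0.5
        },
        {
          "source": "c",
          "weight": 0.5
        }
      ],
      "inhibitors": []
    },
    {
      "name": "pdgfrB",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "b",
          "weight": 0.5
        }
      ],
      "inhibitors": [
        {
          "source": "cdh11",
          "weight": 1
        }
      ]
    },
    {
      "name": "ras",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "pdgfrA",
          "weight": 1
        },
        {
          "source": "pdgfrB",
          "weight": 1
        }
      ],
      "inhibitors": []
    },
    {
      "name": "raf",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "ras",
          "weight": 1
        }
      ],
      "inhibitors": []
    },
    {
      "name": "mek",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "raf",
          "weight": 1
        }
      ],
      "inhibitors": []
    },
    {
      "name": "erk",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "mek",
          "weight": 1
        }
      ],
      "inhibitors": [
        {
          "source": "dusp1",
          "weight": 1
        }
      ]
    },
    {
      "name": "dusp1",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "erk",
          "weight": 1
        }
      ],
      "inhibitors": [
        {
          "source": "Bcat",
          "weight": 1
        }
      ]
    },
    {
      "name": "Bcat",
      "decay": 2,
      "initial": 1,
      "constitutive": true,
      "clamp": null,
      "activators": [],
      "inhibitors": [
        {
          "source": "cdh11",
          "weight": 1
        }
      ]
    },
    {
      "name": "cyclinD1",
      "decay": 1,
      "initial": 0,
      "constitutive": false,
      "clamp": null,
      "activators": [
        {
          "source": "dusp1",
          "weight": 1
        }
      ],
      "inhibitors": []
    }
  ]
}
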