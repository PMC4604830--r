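{
  "matrix_id": "STUDY:demo",
  "citation": "Demo study (synthetic)",
  "taxa": ["TAXON:fishA", "TAXON:tetrapodA", "TAXON:tetrapodB"],
  "characters": [
    {
      "char_id": "c001",
      "label": "humerus shape",
      "states": [
        {
          "state_id": "s1",
          "label": "humerus L-shaped",
          "phenotypes": [
            {
              "entity": "TOY:humerus",
              "quality": "PATO:0000052"
            }
          ]
        },
        {
          "state_id": "s2",
          "label": "humerus absent",
          "phenotypes": [
            {
              "entity": "TOY:humerus",
              "quality": "PATO:0000462"
            }
          ]
        }
      ]
    },
    {
      "char_id": "c002",
      "label": "forelimb bud",
      "states": [
        {
          "state_id": "s1",
          "label": "forelimb bud present",
          "phenotypes": [
            {
              "entity": "TOY:forelimb-bud",
              "quality": "PATO:0000467"
            }
          ]
        },
        {
          "state_id": "s2",
          "label": "forelimb bud absent",
          "phenotypes": [
            {
              "entity": "TOY:organism",
              "quality": "PATO:0002000",
              "related_entity": "TOY:forelimb-bud"
            }
          ]
        }
      ]
    },
    {
      "char_id": "c003",
      "label": "entepicondyle",
      "states": [
        {
          "state_id": "s1",
          "label": "entepicondyle present",
          "phenotypes": [
            {
              "entity": "TOY:entepicondyle",
              "quality": "PATO:0000467"
            }
          ]
        },
        {
          "state_id": "s2",
          "label": "entepicondyle absent",
          "phenotypes": [
            {
              "entity": "TOY:entepicondyle",
              "quality": "PATO:0000462"
            }
          ]
        }
      ]
    }
  ],
  "cells": [
    {
      "taxon": "TAXON:fishA",
      "char_id": "c002",
      "state_ids": "s2"
    },
    {
      "taxon": "TAXON:tetrapodA",
      "char_id": "c001",
      "state_ids": "s1"
    },
    {
      "taxon": "TAXON:tetrapodA",
      "char_id": "c002",
      "state_ids": "s1"
    },
    {
      "taxon": "TAXON:tetrapodB",
      "char_id": "c003",
      "state_ids": ["s1", "s2"]
    }
  ]
}
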