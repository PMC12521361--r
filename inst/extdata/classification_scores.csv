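dataset,group,class,precision,recall,f1
internal_1,PTH0,epiphyseal_bone,0.941,0.986,0.963
internal_1,PTH0,growth_plate,0.974,0.943,0.958
internal_1,PTH0,primary_spongiosa,0.912,0.917,0.914
internal_1,PTH0,secondary_spongiosa,0.994,0.995,0.995
internal_1,PTH20,epiphyseal_bone,0.939,0.969,0.954
internal_1,PTH20,growth_plate,0.957,0.932,0.944
internal_1,PTH20,primary_spongiosa,0.933,0.938,0.935
internal_1,PTH20,secondary_spongiosa,0.994,0.994,0.994
internal_1,PTH40,epiphyseal_bone,0.935,0.957,0.946
internal_1,PTH40,growth_plate,0.937,0.922,0.930
internal_1,PTH40,primary_spongiosa,0.901,0.926,0.913
internal_1,PTH40,secondary_spongiosa,0.996,0.990,0.993
internal_1,PTH80,epiphyseal_bone,0.954,0.968,0.960
internal_1,PTH80,growth_plate,0.963,0.935,0.949
internal_1,PTH80,primary_spongiosa,0.934,0.946,0.940
internal_1,PTH80,secondary_spongiosa,0.992,0.996,0.994
internal_2,SN_0N,epiphyseal_bone,0.958,0.976,0.967
internal_2,SN_0N,growth_plate,0.969,0.939,0.954
internal_2,SN_0N,primary_spongiosa,0.893,0.919,0.906
internal_2,SN_0N,secondary_spongiosa,0.993,0.995,0.994
internal_2,SN_6N,epiphyseal_bone,0.941,0.961,0.951
internal_2,SN_6N,growth_plate,0.946,0.926,0.936
internal_2,SN_6N,primary_spongiosa,0.912,0.933,0.922
internal_2,SN_6N,secondary_spongiosa,0.994,0.992,0.993
internal_2,SN_12N,epiphyseal_bone,0.948,0.975,0.961
internal_2,SN_12N,growth_plate,0.962,0.933,0.947
internal_2,SN_12N,primary_spongiosa,0.885,0.910,0.897
internal_2,SN_12N,secondary_spongiosa,0.994,0.994,0.994
internal_3,aged_19m,epiphyseal_bone,0.947,0.975,0.960
internal_3,aged_19m,growth_plate,0.962,0.939,0.950
internal_3,aged_19m,primary_spongiosa,0.888,0.914,0.901
internal_3,aged_19m,secondary_spongiosa,0.995,0.993,0.994
external,Ris15,epiphyseal_bone,0.978,0.996,0.987
external,Ris15,growth_plate,0.975,0.947,0.961
external,Ris15,primary_spongiosa,0.910,0.910,0.910
external,Ris15,secondary_spongiosa,0.997,0.998,0.997
external,Ris15_ML,epiphyseal_bone,0.982,0.997,0.989
external,Ris15_ML,growth_plate,0.994,0.960,0.977
external,Ris15_ML,primary_spongiosa,0.950,0.921,0.935
external,Ris15_ML,secondary_spongiosa,0.995,0.999,0.997
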