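>CENH3|A|1
KVDQSEVAHWPRHGPVAIKNYALVPLPDSQAWYMGPTWSFGWTNPKWVANTEKFFPPETWPLDMVKAIDKLMVEKIRMDYLENVLQFETRFIKGESASKWHTVQRFSWDYCLEDADMRQPLCNQFCRDITVTSLWAICLQKDVINIFLLQNIRQYQ
>CENH3|B|1
KVDQSEVAHWPRHGPVAIKNYALVPLPDSQAWYMGPTWSFGWTNPKWVANTEKFFPPETWPLDMVKAIDKLMVEKIRMDYLENVLQFETRFVKGESASKWHTVQRFSWDYCLEDADMRQPLCNQFCRDITVTSLWAICLQKDVMNIFLLQNIRQYQ
>DEAH11|A|1
RPLRYNGLFIPRHLTECQSHEMNFSFGYMPAFMYKGVTWISACEHIDNWSWELWKMIICESNRQLYHCDDVDWGMMAISSFRGQGTTTIFCQWFTVIRDWP
>DEAH11|B|1
RPLRYNGLFIPRHLTECQSHEMNFSFGYMPAFMYKGVTWISACEHIDNWSWELWRMIICESNRQLYHCDDVDWGMMAISSFRGQGTTTIFCQWFTVIRDWP
>ESD4|A|1
PGHPAITSNPFMFKNYKCMARRVWIVTKIWLNWTERIADLQLSIRKSPLTPTPFEWRYDDDRHGPHTSNASRPRFVMFIWQIHLHWGAHWRSHYFLRK
>ESD4|B|1
PGHPAITSNPFMFKNYKCMARRVWIVTKIWLNWTERIADL
>ESD4|B|2
PGHPAITSNAFMFKNYKCMARRVWIVTKIWLNWTERIADLQLSIRKSPLTPTPFEWRYDDDRHGPHTSNLSRPRFVMFIWQIHLHWGAHWRSHYFLRK
>SUVH5|A|1
PLRVQMHANICIWGKVHAMWCSTQFIGAQWAFRDHIPRIQMANWNGLDNVILILALDMSHLVIQIQKFGEFQKQFWMNYSIPGIIRCRRAKYLQEKAMICTSPTHFICEKDRLMTYLTEI
>SUVH5|B|1
PLRVQMHANICIWGKVHAMWCSTQFIGAQWAFRDHIPRIQMANWNGLDNVILILALDMSHLVIQIQKFGEFQKQFWMNYSIPGIIRCRRAKYLQEKAMICTSPTHFICEKDRLMTYLTEI
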