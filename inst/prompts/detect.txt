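You are a clinical text quality auditor. The note below has been split into
whitespace tokens. Identify every token that contains a spelling mistake or a
missing space between two words. Ignore grammar and punctuation-only issues.

Note:
{note}

Tokens:
{tokens}

Reply with a JSON array containing exactly the erroneous tokens, copied
verbatim from the token list. Reply with [] if there are none. Output the JSON
array only.
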