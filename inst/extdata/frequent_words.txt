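the
of
and
in
to
a
is
was
for
that
with
as
were
by
on
at
be
are
this
from
or
an
we
which
have
not
has
but
been
their
its
these
than
can
also
using
used
use
between
both
each
during
after
under
over
all
one
two
three
four
five
our
such
may
more
most
other
however
into
only
some
results
result
study
studies
analysis
data
method
methods
figure
table
shown
show
showed
found
observed
significant
significantly
level
levels
expression
control
controls
treatment
treated
sample
samples
group
groups
time
times
activity
effect
effects
increase
increased
decrease
decreased
total
number
based
high
low
different
same
respectively
compared
following
present
described
mean
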